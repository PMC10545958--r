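# Gait loading analytics -------------------------------------------------------

#' Vertical ground reaction force from a pressure series
#'
#' Per frame, GRF is the grid integral of pressure times cell area,
#' converted via 1 kPa * mm^2 = 1e-3 N.
#'
#' @param series a `pressure_series`.
#' @return numeric vector of forces (N), one per frame.
#' @export
compute_grf <- function(series) {
  if (!inherits(series, "pressure_series"))
    stop_input("series must be a pressure_series")
  a <- cell_area(series)
  if (!is.finite(a) || a <= 0) stop_input("missing or invalid cell area")
  d <- dim(series$frames)
  p <- matrix(series$frames, nrow = d[1])
  rowSums(p) * a * 1e-3
}

#' Centre of pressure of a single pressure frame
#'
#' Pressure-area weighted centroid of the cell centres. Frames whose total
#' force does not exceed `threshold` are masked (returned as `NA`).
#'
#' @param frame numeric pressure matrix (kPa), rows heel-to-toe.
#' @param cell_size cell dimensions (mm).
#' @param threshold minimum total force for a valid CoP (N); default 10.
#' @return named numeric `c(x =, y =)` in mm, or `NA`s when masked.
#' @export
compute_cop <- function(frame, cell_size = c(10, 10), threshold = 10) {
  a <- prod(cell_size)
  f <- sum(frame) * a * 1e-3
  if (!is.finite(f) || f <= threshold) return(c(x = NA_real_, y = NA_real_))
  yc <- (row(frame) - 0.5) * cell_size[1]
  xc <- (col(frame) - 0.5) * cell_size[2]
  w <- frame / sum(frame)
  c(x = sum(w * xc), y = sum(w * yc))
}

#' Centre-of-pressure trajectory over a stance series
#'
#' Applies [compute_cop()] per frame. Stance is delimited by the first and
#' last frame with GRF above `threshold`; frames outside stance or below
#' threshold are masked.
#'
#' @param series a `pressure_series`.
#' @param threshold CoP validity / stance detection force threshold (N).
#' @return data.frame with columns `time_s`, `grf_n`, `x_mm`, `y_mm` and
#'   attribute `"stance"` (first/last stance frame indices).
#' @export
cop_trajectory <- function(series, threshold = 10) {
  grf <- compute_grf(series)
  d <- dim(series$frames)
  xy <- t(vapply(seq_len(d[1]), function(i)
    compute_cop(matrix(series$frames[i, , ], d[2], d[3]),
                cell_size = series$cell_size, threshold = threshold),
    numeric(2)))
  on <- which(grf > threshold)
  out <- data.frame(time_s = (seq_len(d[1]) - 1) / series$freq,
                    grf_n = grf, x_mm = xy[, 1], y_mm = xy[, 2])
  attr(out, "stance") <- if (length(on)) c(first = min(on), last = max(on))
                         else c(first = NA_integer_, last = NA_integer_)
  out
}

#' Normalise a CoP trajectory to foot dimensions and stance time
#'
#' Medial-lateral CoP is expressed as a percentage of foot width from the
#' medial edge of the loaded footprint, anterior-posterior as a percentage of
#' foot length from the posterior edge; time is resampled by linear
#' interpolation to 101 points over 0-100% of stance.
#'
#' @param traj data.frame from [cop_trajectory()].
#' @param foot_length,foot_width subject foot dimensions (mm).
#' @return object of class `cop_trajectory_norm`: data.frame with
#'   `pct_stance` (0..100), `x_pct`, `y_pct`.
#' @export
normalize_cop <- function(traj, foot_length, foot_width) {
  if (!is.finite(foot_length) || !is.finite(foot_width) ||
      foot_length <= 0 || foot_width <= 0)
    stop_param("foot dimensions must be positive")
  st <- attr(traj, "stance")
  if (is.null(st) || any(is.na(st))) stop_input("trajectory has no stance phase")
  idx <- st["first"]:st["last"]
  x <- traj$x_mm[idx]; y <- traj$y_mm[idx]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2) stop_input("not enough valid CoP samples in stance")
  # footprint origin: most medial / most posterior valid CoP support
  x0 <- min(x[ok]); y0 <- min(y[ok])
  ts <- seq_along(idx)
  target <- seq(1, length(idx), length.out = 101)
  xi <- approx(ts[ok], x[ok], xout = target, rule = 2)$y
  yi <- approx(ts[ok], y[ok], xout = target, rule = 2)$y
  out <- data.frame(pct_stance = seq(0, 100, length.out = 101),
                    x_pct = 100 * (xi - x0) / foot_width,
                    y_pct = 100 * (yi - y0) / foot_length)
  class(out) <- c("cop_trajectory_norm", "data.frame")
  out
}

#' Regional peak and mean plantar pressure
#'
#' Peak is the maximum over a region's cells and all stance frames; mean is
#' the time-and-area weighted average pressure over stance (all cells of the
#' region, all stance frames). Empty regions are reported as zero with a
#' warning.
#'
#' @param series a `pressure_series`.
#' @param regions a `region_map` covering the series grid.
#' @param threshold stance detection threshold on GRF (N).
#' @return data.frame with columns `region`, `peak_kpa`, `mean_kpa`.
#' @export
regional_stats <- function(series, regions, threshold = 10) {
  d <- dim(series$frames)
  if (!all(dim(regions) == d[2:3]))
    stop_input("region map does not cover the pressure grid")
  grf <- compute_grf(series)
  on <- which(grf > threshold)
  if (!length(on)) on <- seq_len(d[1])
  labs <- sort(unique(stats::na.omit(as.vector(regions))))
  res <- lapply(labs, function(r) {
    cells <- which(regions == r)
    if (!length(cells)) {
      warning("empty region: ", r)
      return(data.frame(region = r, peak_kpa = 0, mean_kpa = 0))
    }
    sub <- matrix(series$frames[on, , , drop = FALSE],
                  nrow = length(on))[, cells, drop = FALSE]
    data.frame(region = r, peak_kpa = max(sub), mean_kpa = mean(sub))
  })
  do.call(rbind, res)
}
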