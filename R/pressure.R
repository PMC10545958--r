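# Plantar pressure series and region maps -------------------------------------

# anatomical band boundaries as fractions of foot length from the heel
BAND_REAR <- 0.31
BAND_MID <- 0.55
BAND_FORE <- 0.82

#' Construct a plantar pressure series
#'
#' A stance-phase series of plantar pressure grids sampled at `freq` Hz on a
#' rectangular sensor grid. Rows of the grid run from heel (row 1) to toe;
#' columns from medial (column 1) to lateral. Pressures are in kPa; every
#' cell has the same rectangular area.
#'
#' @param frames numeric array `n_frames x nrow x ncol` of pressures (kPa).
#' @param cell_size length-2 cell dimensions, (length-wise, width-wise) mm.
#' @param freq sampling frequency (Hz).
#' @param meta optional metadata list (archetype, shares, ...).
#' @return an object of class `pressure_series`.
#' @export
pressure_series <- function(frames, cell_size = c(10, 10), freq = 50,
                            meta = list()) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L)
    stop_input("frames must be a 3-d array (frame, row, col)")
  if (any(frames < 0)) stop_input("pressures must be nonnegative")
  structure(list(frames = frames, cell_size = as.numeric(cell_size),
                 freq = freq, meta = meta),
            class = "pressure_series")
}

#' @export
print.pressure_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("pressure_series: %d frames @ %g Hz, %dx%d grid (%gx%g mm cells)\n",
              d[1], x$freq, d[2], d[3], x$cell_size[1], x$cell_size[2]))
  cat(sprintf("  peak pressure %.1f kPa\n", max(x$frames)))
  invisible(x)
}

#' Cell area of a pressure grid (mm^2)
#' @param series a `pressure_series`.
#' @return scalar cell area.
#' @export
cell_area <- function(series) prod(series$cell_size)

#' Cell-centre coordinates of a pressure grid
#'
#' @param series a `pressure_series`.
#' @return list with vectors `y` (heel-to-toe, mm) and `x` (medial-to-lateral,
#'   mm), plus matrices `xc`, `yc` matching the grid layout.
#' @export
grid_centers <- function(series) {
  d <- dim(series$frames)
  y <- (seq_len(d[2]) - 0.5) * series$cell_size[1]
  x <- (seq_len(d[3]) - 0.5) * series$cell_size[2]
  list(y = y, x = x,
       yc = matrix(y, d[2], d[3]), xc = matrix(x, d[2], d[3], byrow = TRUE))
}

#' Map pressure grid cells to anatomical plantar regions
#'
#' Cells are banded by their fractional position from the heel (rearfoot
#' < 0.31, midfoot < 0.55, forefoot < 0.82, toes beyond) and split
#' medially/laterally at mid width. The NF scheme has 8 regions; HB drops
#' the lesser toes and midfoot (5 regions, the medial toe band is the
#' hallux); FB additionally drops the hallux (4 regions). Cells in bands a
#' scheme does not cover are `NA` (they carry no load for that foot type).
#'
#' @param grid_shape integer length-2, grid rows x cols.
#' @param scheme `"NF"`, `"HB"` or `"FB"`.
#' @return character matrix of region labels (class `region_map`), `NA` for
#'   uncovered cells; attribute `"scheme"` records the foot type.
#' @export
region_map <- function(grid_shape, scheme = c("NF", "HB", "FB")) {
  scheme <- match.arg(scheme)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  if (nr < 4L || nc < 4L) stop_param("grid must be at least 4x4")
  fy <- (row(matrix(0, nr, nc)) - 0.5) / nr
  fx <- (col(matrix(0, nr, nc)) - 0.5) / nc
  med <- fx < 0.5
  band <- ifelse(fy < BAND_REAR, "rear",
          ifelse(fy < BAND_MID, "mid",
          ifelse(fy < BAND_FORE, "fore", "toes")))
  lab <- matrix(NA_character_, nr, nc)
  lab[band == "rear" & med] <- "medial_rearfoot"
  lab[band == "rear" & !med] <- "lateral_rearfoot"
  lab[band == "fore" & med] <- "medial_forefoot"
  lab[band == "fore" & !med] <- "lateral_forefoot"
  if (scheme == "NF") {
    lab[band == "mid" & med] <- "medial_midfoot"
    lab[band == "mid" & !med] <- "lateral_midfoot"
    lab[band == "toes" & fx < 0.45] <- "hallux"
    lab[band == "toes" & fx >= 0.45] <- "other_toes"
  } else if (scheme == "HB") {
    lab[band == "toes" & fx < 0.45] <- "hallux"
  }
  structure(lab, class = c("region_map", "matrix"), scheme = scheme)
}

# per-region temporal load profiles over normalised stance time (0..1);
# heel loads early, forefoot/toes late, midfoot between
region_time_profile <- function(region, t) {
  p <- switch(sub("^(medial|lateral)_", "", region),
    rearfoot = dnorm(t, 0.22, 0.13),
    midfoot = dnorm(t, 0.45, 0.15),
    forefoot = dnorm(t, 0.72, 0.13),
    hallux = dnorm(t, 0.82, 0.10),
    other_toes = dnorm(t, 0.80, 0.10),
    stop_input("unknown region: ", region))
  p
}

#' Generate a synthetic stance-phase plantar pressure series
#'
#' Constructs a Pedar-like 50 Hz pressure grid series for one stance of the
#' given archetype. The instantaneous whole-grid force follows a two-peak
#' walking template (weight acceptance and push-off peaks of 1.1 body
#' weight); regional load time-integrals are matched to the archetype's
#' `regional_load_shares` by iterative proportional fitting of a
#' region-by-time load matrix whose temporal profiles migrate heel to toe.
#' Within each frame a region's force is spread uniformly over its cells, so
#' regions absent from the archetype's scheme (toes/midfoot in HB/FB) are
#' identically zero. Optional multiplicative per-frame, per-region noise
#' (`noise_cv`) emulates trial-to-trial variability.
#'
#' @param params an `archetype_params`.
#' @param n_frames number of stance frames (>= 10) at 50 Hz.
#' @param grid_shape sensor grid rows x cols (>= 4x4).
#' @param cell_size sensor cell dimensions (mm).
#' @param noise_cv coefficient of variation of multiplicative load noise;
#'   0.005 by default (deterministic template with slight trial texture).
#' @param trial integer mixed into the seed so repeated trials differ.
#' @return a `pressure_series` with metadata `archetype`, `shares`, `regions`.
#' @export
generate_pressure_series <- function(params, n_frames = 51L,
                                     grid_shape = c(16L, 6L),
                                     cell_size = c(10, 10),
                                     noise_cv = 0.005, trial = 0L) {
  if (!inherits(params, "archetype_params"))
    stop_param("params must be an archetype_params object")
  if (n_frames < 10L) stop_param("n_frames must be >= 10")
  if (grid_shape[1] < 4L || grid_shape[2] < 4L)
    stop_param("grid must be at least 4x4")
  rmap <- region_map(grid_shape, params$archetype)
  shares <- params$regional_load_shares
  regions <- names(shares)
  tt <- seq(0, 1, length.out = n_frames)
  bw <- params$body_mass * 9.81
  # two-peak vertical GRF template, each peak scaled to 1.1 BW
  g <- exp(-((tt - 0.25) / 0.10)^2 / 2) + exp(-((tt - 0.75) / 0.10)^2 / 2)
  g <- g / max(g) * 1.1 * bw
  # initial region-by-time matrix, then Sinkhorn balancing:
  # rows (frames) match g, columns match share * total impulse
  M <- sapply(regions, function(r) shares[[r]] *
                pmax(region_time_profile(r, tt), 1e-12))
  M <- matrix(M, nrow = n_frames)
  col_target <- shares * sum(g)
  for (it in 1:80) {
    cs <- colSums(M)
    M <- sweep(M, 2, ifelse(cs > 0, col_target / cs, 0), "*")
    rs <- rowSums(M)
    M <- sweep(M, 1, ifelse(rs > 0, g / rs, 0), "*")
  }
  if (noise_cv > 0) {
    eta <- with_seed(params$seed * 1000L + as.integer(trial) + 1L,
                     matrix(rnorm(length(M), 0, noise_cv), nrow(M)))
    M <- M * pmax(1 + eta, 0)
  }
  # spread region force uniformly over the region's cells
  area <- prod(cell_size)
  frames <- array(0, dim = c(n_frames, grid_shape[1], grid_shape[2]))
  for (j in seq_along(regions)) {
    cells <- which(rmap == regions[j])
    if (!length(cells)) next
    # pressure kPa = 1000 * N / mm^2
    p_cell <- 1000 * M[, j] / (length(cells) * area)
    for (cl in cells) {
      ij <- arrayInd(cl, grid_shape)
      frames[, ij[1], ij[2]] <- frames[, ij[1], ij[2]] + p_cell
    }
  }
  pressure_series(frames, cell_size = cell_size, freq = 50,
                  meta = list(archetype = params$archetype,
                              shares = shares,
                              seed = params$seed, trial = trial,
                              body_weight_N = bw,
                              foot_length = params$foot_length,
                              foot_width = params$foot_width))
}

#' Region centroid coordinates of a region map on a grid
#' @param rmap a `region_map`.
#' @param cell_size cell dimensions (mm).
#' @return matrix with rows per region: centroid x and y (mm).
#' @export
region_centroids <- function(rmap, cell_size = c(10, 10)) {
  regions <- sort(unique(stats::na.omit(as.vector(rmap))))
  nr <- nrow(rmap); nc <- ncol(rmap)
  yc <- (row(rmap) - 0.5) * cell_size[1]
  xc <- (col(rmap) - 0.5) * cell_size[2]
  out <- t(vapply(regions, function(r) {
    sel <- which(rmap == r)
    c(x = mean(xc[sel]), y = mean(yc[sel]))
  }, numeric(2)))
  out
}
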