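# Permutation cluster test for 1-D stance curves -------------------------------

# pointwise pooled two-sample t statistic; 0 where variance vanishes
pointwise_t <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, var); vb <- apply(B, 2, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[!is.finite(tt)] <- 0
  tt
}

# supra-threshold clusters of |t|; returns list of (start, end, mass)
t_clusters <- function(tt, thresh) {
  supra <- abs(tt) > thresh
  if (!any(supra)) return(list())
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    list(start = starts[k], end = ends[k],
         mass = sum(abs(tt[i]) - thresh))
  })
}

#' Permutation cluster comparison of two groups of stance curves
#'
#' Non-parametric cluster-level inference for one-dimensional curves on a
#' common 101-point percent-stance base (the Maris-Oostenveld procedure).
#' A pointwise pooled two-sample t statistic is thresholded at the two-sided
#' parametric critical value for `alpha`; contiguous supra-threshold runs are
#' scored by cluster mass (summed threshold exceedance), and each observed
#' cluster's p-value is the fraction of label permutations whose maximum
#' cluster mass is at least as large. All `choose(nA+nB, nA)` relabelings are
#' enumerated when there are at most 500; otherwise `n_perm` Monte-Carlo
#' draws are used with the given seed. Note that with very few trials the
#' attainable p-values are coarse (3+3 trials give 20 relabelings, so the
#' smallest possible p is 0.05).
#'
#' @param trials_A,trials_B numeric matrices, one row per trial, columns a
#'   common time base (typically 101 percent-stance points).
#' @param alpha cluster significance level (and pointwise threshold level).
#' @param n_perm Monte-Carlo permutations when full enumeration exceeds 500.
#' @param seed RNG seed for Monte-Carlo permutations.
#' @return object of class `interval_report`: data.frame with columns
#'   `start_pct`, `end_pct`, `p_value` (only clusters with `p <= alpha`);
#'   attributes `"t"` (pointwise statistic), `"threshold"`, `"n_perm_used"`,
#'   `"all_clusters"` (every supra-threshold cluster with its p).
#' @export
compare_curves <- function(trials_A, trials_B, alpha = 0.05, n_perm = 500L,
                           seed = 0L) {
  A <- as.matrix(trials_A); B <- as.matrix(trials_B)
  if (ncol(A) != ncol(B)) stop_input("curve lengths differ between groups")
  if (nrow(A) < 2L || nrow(B) < 2L) stop_input("need >= 2 trials per group")
  na <- nrow(A); nb <- nrow(B); n <- na + nb
  X <- rbind(A, B)
  q <- ncol(A)
  thresh <- qt(1 - alpha / 2, df = n - 2)
  t_obs <- pointwise_t(A, B)
  obs <- t_clusters(t_obs, thresh)
  pct <- seq(0, 100, length.out = q)

  n_all <- choose(n, na)
  if (n_all <= 500) {
    sel <- combn(n, na)
    perms <- lapply(seq_len(ncol(sel)), function(j) sel[, j])
    exact <- TRUE
  } else {
    perms <- with_seed(seed, lapply(seq_len(n_perm), function(j)
      sample.int(n, na)))
    exact <- FALSE
  }
  max_mass <- vapply(perms, function(ia) {
    cl <- t_clusters(pointwise_t(X[ia, , drop = FALSE],
                                 X[-ia, , drop = FALSE]), thresh)
    if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
  }, numeric(1))

  pval <- function(mass) {
    if (exact) mean(max_mass >= mass - 1e-12)
    else (1 + sum(max_mass >= mass - 1e-12)) / (1 + length(max_mass))
  }
  all_cl <- do.call(rbind, lapply(obs, function(cl)
    data.frame(start_pct = pct[cl$start], end_pct = pct[cl$end],
               mass = cl$mass, p_value = pval(cl$mass))))
  if (is.null(all_cl))
    all_cl <- data.frame(start_pct = numeric(0), end_pct = numeric(0),
                         mass = numeric(0), p_value = numeric(0))
  sig <- all_cl[all_cl$p_value <= alpha, c("start_pct", "end_pct", "p_value"),
                drop = FALSE]
  rownames(sig) <- NULL
  structure(sig, class = c("interval_report", "data.frame"),
            t = t_obs, threshold = thresh,
            n_perm_used = length(perms), exact = exact, all_clusters = all_cl)
}

#' @export
print.interval_report <- function(x, ...) {
  cat("interval_report:", nrow(x), "significant cluster(s); threshold |t| >",
      round(attr(x, "threshold"), 3), "\n")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
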