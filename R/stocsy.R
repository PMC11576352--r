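# Statistical Total Correlation Spectroscopy: one driver variable correlated
# against the whole spectrum, plus intensity-based variable ranking.

#' STOCSY from a driver chemical shift
#'
#' Correlates the intensity at a driver variable against every variable
#' across samples. Peaks belonging to the same molecule show correlations
#' near 1, which aids structural assignment of signals picked from loading
#' plots. The driver is selected by ppm and snapped to the nearest grid point
#' (the snap distance is returned). Correlation is Pearson; covariance uses
#' the n-1 denominator. Zero-variance columns receive correlation 0 by
#' convention.
#'
#' This is typically run on the normalized but unscaled matrix so the
#' covariance trace keeps lineshape-like intensity meaning.
#'
#' @param m A [spectra_matrix] with at least 3 samples.
#' @param driver_ppm Chemical shift of the driver variable.
#' @return List of class `stocsy_result`: `driver_ppm` (snapped),
#'   `driver_index`, `snap_distance`, `ppm`, `correlation`, `covariance`.
#' @export
stocsy <- function(m, driver_ppm) {
  if (nrow(m$X) < 3L) stop("STOCSY requires at least 3 samples")
  d <- snap_ppm(m$ppm, driver_ppm)
  x_d <- m$X[, d]
  if (stats::sd(x_d) == 0) {
    sds <- apply(m$X, 2, stats::sd)
    cand <- which(sds > 0)
    if (length(cand) == 0) stop("driver column is constant and no non-constant column exists")
    near <- cand[which.min(abs(m$ppm[cand] - m$ppm[d]))]
    stop(sprintf("driver column at %.4f ppm is constant; nearest non-constant variable is %.4f ppm",
                 m$ppm[d], m$ppm[near]))
  }
  covv <- drop(stats::cov(x_d, m$X))
  sds <- apply(m$X, 2, stats::sd)
  corr <- ifelse(sds > 0, covv / (stats::sd(x_d) * sds), 0)
  structure(list(driver_ppm = m$ppm[d], driver_index = as.integer(d),
                 snap_distance = attr(d, "snap_distance"),
                 ppm = m$ppm, correlation = corr, covariance = covv),
            class = "stocsy_result")
}

#' @export
print.stocsy_result <- function(x, ...) {
  cat(sprintf("<stocsy_result> driver %.4f ppm; %d variables; max |r| off-driver %.3f\n",
              x$driver_ppm, length(x$ppm),
              max(abs(x$correlation[-x$driver_index]))))
  invisible(x)
}

#' Rank variables by a per-column intensity statistic
#'
#' Orders chemical-shift variables by descending median, mean or maximum
#' intensity across samples — a quick read of which signals are most
#' abundant. Ties are broken by descending ppm so the ranking is
#' deterministic.
#'
#' @param m A [spectra_matrix].
#' @param statistic `"median"` (default), `"mean"` or `"max"`.
#' @return Data frame with columns `ppm` and `value`, ordered by descending
#'   `value` (ties: descending ppm).
#' @export
rank_variables <- function(m, statistic = c("median", "mean", "max")) {
  statistic <- match.arg(statistic)
  v <- switch(statistic,
              median = apply(m$X, 2, stats::median),
              mean = colMeans(m$X),
              max = apply(m$X, 2, max))
  ord <- order(-v, -m$ppm)
  data.frame(ppm = m$ppm[ord], value = v[ord])
}
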