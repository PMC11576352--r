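# Reference-pattern matching: extract a peak template from one clean
# spectrum, scan it against every spectrum with an integer-lag shift
# tolerance using Pearson correlation (amplitude-invariant), threshold the
# best correlation to decide which samples contain the pattern, rank matches
# by matched-window intensity, and iterate with STOCSY to refine.

#' Extract a reference pattern from one spectrum
#'
#' Takes one sample's intensities over a ppm window — chosen by the analyst
#' from a clear, non-overlapped, high-intensity spectrum — and stores the
#' mean-subtracted trace as the matching template.
#'
#' @param m A [spectra_matrix].
#' @param sample_id Source sample.
#' @param ppm_hi,ppm_lo Window bounds (`ppm_hi > ppm_lo`), covering at least
#'   5 grid points.
#' @return List of class `reference_pattern`: `source_sample`, `ppm_window`,
#'   `window_indices` (grid index range), `window_ppm`, `template`
#'   (mean-subtracted intensities).
#' @export
extract_reference <- function(m, sample_id, ppm_hi, ppm_lo) {
  if (!sample_id %in% sample_ids(m)) stop("unknown sample id: ", sample_id)
  if (!(ppm_hi > ppm_lo)) stop("window must have ppm_hi > ppm_lo")
  win <- which(m$ppm <= ppm_hi & m$ppm >= ppm_lo)
  if (length(win) < 5L)
    stop(sprintf("window [%g, %g] covers %d grid points; need >= 5",
                 ppm_hi, ppm_lo, length(win)))
  tr <- m$X[sample_id, win]
  if (stats::sd(tr) == 0) stop("no pattern in window: template is constant")
  structure(list(source_sample = sample_id, ppm_window = c(ppm_hi, ppm_lo),
                 window_indices = win, window_ppm = m$ppm[win],
                 template = tr - mean(tr)),
            class = "reference_pattern")
}

#' Match a reference pattern against every spectrum
#'
#' For each sample and each integer lag in `[-max_shift_points,
#' +max_shift_points]`, the Pearson correlation between the template and the
#' lag-shifted window of that sample is computed; the best correlation over
#' lags (ties: smallest `|lag|`, then the negative lag) decides the match.
#' Samples whose best correlation reaches `threshold` are counted as
#' containing the pattern; the correlation is amplitude-invariant, so
#' abundance is reported separately as the maximum intensity inside the
#' matched window, and samples are ranked by it.
#'
#' @param m A [spectra_matrix].
#' @param pattern A [extract_reference] result.
#' @param max_shift_points Non-negative integer shift tolerance in grid
#'   points.
#' @param threshold Correlation threshold in (0, 1].
#' @return List of class `compass_result`: per-sample vectors
#'   `best_correlation`, `best_shift`, `matched_intensity`,
#'   `contains_pattern`; `n_containing`; `ranking` (all sample ids by
#'   descending matched intensity); plus the echoed `threshold`,
#'   `max_shift_points`.
#' @export
compass_match <- function(m, pattern, max_shift_points = 3, threshold = 0.8) {
  stopifnot(max_shift_points >= 0, threshold > 0, threshold <= 1)
  win <- pattern$window_indices
  p <- ncol(m$X)
  lo_ok <- win[1] - max_shift_points >= 1L
  hi_ok <- win[length(win)] + max_shift_points <= p
  if (!lo_ok || !hi_ok) {
    adm <- min(win[1] - 1L, p - win[length(win)])
    stop(sprintf("window plus shift exceeds the grid; admissible max_shift_points is %d", adm))
  }
  lags <- seq(-max_shift_points, max_shift_points)
  # preferred tie order: |lag| ascending, negative first
  lag_order <- lags[order(abs(lags), lags)]
  n <- nrow(m$X)
  tmpl <- pattern$template
  best_r <- rep(-Inf, n)
  best_lag <- integer(n)
  for (lg in lag_order) {
    Xw <- m$X[, win + lg, drop = FALSE]
    sds <- apply(Xw, 1, stats::sd)
    r <- rep(NA_real_, n)
    ok <- sds > 0
    if (any(ok))
      r[ok] <- drop(stats::cor(tmpl, t(Xw[ok, , drop = FALSE])))
    r[!ok] <- 0  # flat window cannot carry the pattern
    better <- r > best_r  # strict: earlier lags in tie order win ties
    best_r[better] <- r[better]
    best_lag[better] <- lg
  }
  ids <- sample_ids(m)
  matched_int <- vapply(seq_len(n), function(i)
    max(m$X[i, win + best_lag[i]]), numeric(1))
  contains <- best_r >= threshold
  ranking <- ids[order(-matched_int, ids)]
  structure(list(best_correlation = stats::setNames(best_r, ids),
                 best_shift = stats::setNames(best_lag, ids),
                 matched_intensity = stats::setNames(matched_int, ids),
                 contains_pattern = stats::setNames(contains, ids),
                 n_containing = sum(contains),
                 ranking = ranking,
                 threshold = threshold,
                 max_shift_points = max_shift_points),
            class = "compass_result")
}

#' @export
print.compass_result <- function(x, ...) {
  cat(sprintf("<compass_result> %d/%d samples contain the pattern (threshold %.2f, max shift %d)\n",
              x$n_containing, length(x$best_correlation), x$threshold,
              x$max_shift_points))
  invisible(x)
}

#' One pattern-matching / STOCSY refinement iteration
#'
#' Runs [compass_match], restricts the matrix to the samples containing the
#' pattern, drives a STOCSY at the template's apex ppm on that subset (which
#' surfaces the molecule's other resonances), and refines the template as
#' the mean of the matched, lag-aligned windows (mean-subtracted). One
#' iteration per call; callers may loop until the matched set stabilizes.
#'
#' @param m A [spectra_matrix].
#' @param pattern A [extract_reference] result.
#' @param max_shift_points,threshold As in [compass_match].
#' @return List with `compass` (the [compass_match] result), `stocsy` (the
#'   subset [stocsy] result) and `pattern` (refined `reference_pattern`,
#'   same window, source `"refined"`).
#' @export
compass_stocsy_iterate <- function(m, pattern, max_shift_points = 3,
                                   threshold = 0.8) {
  cm <- compass_match(m, pattern, max_shift_points, threshold)
  hit_ids <- names(cm$contains_pattern)[cm$contains_pattern]
  if (length(hit_ids) == 0)
    stop("no samples matched the pattern; lower the threshold")
  sub <- subset_samples(m, hit_ids)
  apex_ppm <- pattern$window_ppm[which.max(pattern$template)]
  st <- stocsy(sub, apex_ppm)
  win <- pattern$window_indices
  aligned <- t(vapply(hit_ids, function(id)
    m$X[id, win + cm$best_shift[[id]]], numeric(length(win))))
  tmpl <- colMeans(aligned)
  refined <- structure(list(source_sample = "refined",
                            ppm_window = pattern$ppm_window,
                            window_indices = win,
                            window_ppm = pattern$window_ppm,
                            template = tmpl - mean(tmpl)),
                       class = "reference_pattern")
  list(compass = cm, stocsy = st, pattern = refined)
}
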