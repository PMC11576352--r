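#' Single 1D NMR spectrum
#'
#' Container for one processed 1D spectrum: a chemical-shift axis in ppm and
#' the matching intensity trace. The ppm axis is stored strictly descending
#' (NMR display convention); ascending input is reversed on construction.
#'
#' @param sample_id Single non-empty string identifying the sample.
#' @param ppm Strictly monotone numeric vector of chemical shifts (ppm),
#'   length >= 2. Either direction is accepted; stored descending.
#' @param intensity Numeric vector, same length as `ppm`.
#' @param meta Named list of free-form metadata strings (e.g. spectrometer
#'   frequency in MHz, source file).
#' @return An object of class `nmr_spectrum` with fields `sample_id`, `ppm`,
#'   `intensity`, `meta`.
#' @export
nmr_spectrum <- function(sample_id, ppm, intensity, meta = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) < 2L || length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length >= 2")
  d <- diff(ppm)
  if (all(d > 0)) {          # ascending input: flip to canonical descending
    ppm <- rev(ppm); intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone")
  }
  if (!all(is.finite(intensity))) stop("intensity contains non-finite values")
  structure(list(sample_id = sample_id, ppm = ppm, intensity = intensity,
                 meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s: %d points, %.4f..%.4f ppm\n",
              x$sample_id, length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Spectral data matrix on a shared ppm grid
#'
#' n samples by p chemical-shift variables. Row names of `X` carry the sample
#' identifiers; the grid is strictly descending.
#'
#' @param X Numeric matrix, n samples x p variables, all values finite.
#' @param ppm Strictly descending numeric vector of length `ncol(X)`.
#' @param sample_ids Character vector of unique sample identifiers, length
#'   `nrow(X)`; defaults to existing row names of `X`.
#' @return An object of class `spectra_matrix` with fields `X` (row names =
#'   sample ids) and `ppm`.
#' @export
spectra_matrix <- function(X, ppm, sample_ids = rownames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  ppm <- as.numeric(ppm)
  if (length(ppm) != ncol(X)) stop("length(ppm) must equal ncol(X)")
  if (length(ppm) > 1L && !all(diff(ppm) < 0))
    stop("ppm grid must be strictly descending")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) stop("one sample id per row required")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0)
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(X))) stop("X contains non-finite values")
  rownames(X) <- sample_ids
  colnames(X) <- NULL
  structure(list(X = X, ppm = ppm), class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d variables, %.4f..%.4f ppm\n",
              nrow(x$X), ncol(x$X), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' @export
dim.spectra_matrix <- function(x) dim(x$X)

#' Sample identifiers of a spectra matrix
#' @param m A `spectra_matrix`.
#' @return Character vector of sample ids (row order).
#' @export
sample_ids <- function(m) rownames(m$X)

#' Subset a spectra matrix by sample
#' @param m A `spectra_matrix`.
#' @param ids Character vector of sample ids to keep (order preserved as given).
#' @return A `spectra_matrix` restricted to `ids`.
#' @export
subset_samples <- function(m, ids) {
  missing <- setdiff(ids, sample_ids(m))
  if (length(missing) > 0)
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  spectra_matrix(m$X[ids, , drop = FALSE], m$ppm, ids)
}

# Index of the grid point nearest to a requested ppm; snap distance returned
# as an attribute so callers can log it.
snap_ppm <- function(ppm_grid, ppm) {
  idx <- which.min(abs(ppm_grid - ppm))
  structure(idx, snap_distance = abs(ppm_grid[idx] - ppm))
}

# Check two grids agree exactly; error names the first mismatched ppm.
check_same_grid <- function(grid_a, grid_b) {
  if (length(grid_a) != length(grid_b))
    stop(sprintf("ppm grid mismatch: %d vs %d points",
                 length(grid_a), length(grid_b)))
  bad <- which(grid_a != grid_b)
  if (length(bad) > 0)
    stop(sprintf("ppm grid mismatch at position %d: %.6g vs %.6g",
                 bad[1], grid_a[bad[1]], grid_b[bad[1]]))
  invisible(TRUE)
}
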