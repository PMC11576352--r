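# Region exclusion, normalization and variable scaling with full provenance.
# Fixed pipeline order: exclusion -> normalization -> scaling, so excluded
# signal (e.g. residual water) never influences dilution factors.

#' Default excluded spectral region (residual water)
#'
#' The conventional water suppression residual window for aqueous biofluids,
#' 4.55-4.90 ppm. Nothing is excluded unless explicitly requested; this
#' constant is a convenience for callers.
#' @return A one-row matrix `cbind(ppm_hi, ppm_lo)`.
#' @export
water_region <- function() cbind(ppm_hi = 4.90, ppm_lo = 4.55)

#' Remove spectral regions
#'
#' Drops every grid column whose ppm lies inside any of the closed intervals
#' `[ppm_lo, ppm_hi]`; the order of the surviving columns is preserved.
#'
#' @param m A [spectra_matrix].
#' @param regions Two-column matrix (or list of length-2 vectors) of
#'   `c(ppm_hi, ppm_lo)` intervals with `ppm_hi > ppm_lo`. An empty set of
#'   regions returns `m` unchanged.
#' @return A [spectra_matrix] without the excluded columns.
#' @export
exclude_regions <- function(m, regions) {
  regions <- as_region_matrix(regions)
  if (nrow(regions) == 0) return(m)
  drop <- rep(FALSE, length(m$ppm))
  for (k in seq_len(nrow(regions))) {
    hi <- regions[k, 1]; lo <- regions[k, 2]
    if (!(hi > lo)) stop("region must have ppm_hi > ppm_lo")
    drop <- drop | (m$ppm >= lo & m$ppm <= hi)
  }
  if (all(drop)) stop("all grid columns excluded; at least one must survive")
  spectra_matrix(m$X[, !drop, drop = FALSE], m$ppm[!drop], sample_ids(m))
}

as_region_matrix <- function(regions) {
  if (is.null(regions) || length(regions) == 0)
    return(matrix(numeric(0), ncol = 2))
  if (is.list(regions)) regions <- do.call(rbind, regions)
  regions <- matrix(as.numeric(regions), ncol = 2)
  regions
}

#' Total-area normalization
#'
#' Divides each spectrum by `row_sum / area_target` so every row integrates to
#' the same constant; the divisors are reported as per-sample dilution
#' factors.
#'
#' @param m A [spectra_matrix]; every row must have a positive intensity sum.
#' @param area_target Positive target row sum (default 100, a common
#'   convention for normalized NMR profiles).
#' @return List of class `preprocess_result`: `matrix` (normalized
#'   [spectra_matrix]) and `dilution_factors` (named numeric, the divisors).
#' @export
normalize_total_area <- function(m, area_target = 100) {
  stopifnot(area_target > 0)
  sums <- rowSums(m$X)
  bad <- sums <= 0
  if (any(bad))
    stop("non-positive total area for sample(s): ",
         paste(sample_ids(m)[bad], collapse = ", "))
  factors <- sums / area_target
  Xn <- m$X / factors
  structure(list(matrix = spectra_matrix(Xn, m$ppm, sample_ids(m)),
                 dilution_factors = stats::setNames(factors, sample_ids(m))),
            class = "preprocess_result")
}

#' Probabilistic quotient normalization (PQN)
#'
#' Estimates a per-sample dilution factor as the median of the quotients
#' between the sample and a reference spectrum (the element-wise median
#' spectrum across samples), then divides the sample by that factor.
#' Total-area normalization to `area_target` is always applied first, which
#' makes the quotients scale-free; the reported dilution factors are the
#' product of the total-area divisor and the median quotient.
#'
#' @param m A [spectra_matrix] with at least 2 samples.
#' @param reference Reference spectrum rule; only `"median_spectrum"` is
#'   implemented.
#' @param area_target Target row sum for the internal total-area step.
#' @return A `preprocess_result` with the normalized `matrix`,
#'   `dilution_factors` (combined divisor per sample) and `pqn_quotients`
#'   (the median-quotient part alone).
#' @export
normalize_pqn <- function(m, reference = "median_spectrum", area_target = 100) {
  reference <- match.arg(reference, "median_spectrum")
  if (nrow(m$X) < 2L) stop("PQN requires at least 2 samples")
  ta <- normalize_total_area(m, area_target)
  Xa <- ta$matrix$X
  ref <- apply(Xa, 2, stats::median)
  usable <- ref > 0
  if (!any(usable)) stop("PQN reference spectrum is all zeros")
  q <- apply(Xa[, usable, drop = FALSE], 1,
             function(x) stats::median(x / ref[usable]))
  Xn <- Xa / q
  structure(list(matrix = spectra_matrix(Xn, m$ppm, sample_ids(m)),
                 dilution_factors = ta$dilution_factors * q,
                 pqn_quotients = stats::setNames(q, sample_ids(m))),
            class = "preprocess_result")
}

#' Variable scaling
#'
#' Column-wise scaling of a spectral matrix: mean-centering (`"center"`),
#' unit-variance (`"uv"`, autoscaling) or Pareto (`"pareto"`, division of the
#' centered column by the square root of its standard deviation, damping the
#' dominance of intense peaks). Standard deviations use the n-1 denominator.
#' Zero-variance columns are dropped under `"uv"`/`"pareto"` with a warning.
#'
#' @param m A [spectra_matrix].
#' @param method One of `"none"`, `"center"`, `"uv"`, `"pareto"`.
#' @return A `preprocess_result` with `matrix`, `centers`, `scales` (the
#'   applied per-variable values; `scales` is 1 for `"none"`/`"center"`) and
#'   `dropped_ppm` (zero-variance columns removed, possibly empty).
#' @export
scale_variables <- function(m, method = c("none", "center", "uv", "pareto")) {
  method <- match.arg(method)
  X <- m$X
  ppm <- m$ppm
  dropped <- numeric(0)
  if (method == "none") {
    centers <- rep(0, ncol(X)); scales <- rep(1, ncol(X))
  } else {
    if (nrow(X) < 2L && method != "center")
      stop("uv/pareto scaling requires at least 2 samples")
    centers <- colMeans(X)
    if (method == "center") {
      scales <- rep(1, ncol(X))
    } else {
      sds <- apply(X, 2, stats::sd)
      zero <- sds == 0
      if (any(zero)) {
        warning(sprintf("%d zero-variance column(s) dropped before %s scaling",
                        sum(zero), method))
        dropped <- ppm[zero]
        X <- X[, !zero, drop = FALSE]
        ppm <- ppm[!zero]
        centers <- centers[!zero]
        sds <- sds[!zero]
      }
      scales <- if (method == "uv") sds else sqrt(sds)
    }
    X <- sweep(X, 2, centers, "-")
    X <- sweep(X, 2, scales, "/")
  }
  structure(list(matrix = spectra_matrix(X, ppm, sample_ids(m)),
                 centers = centers, scales = scales, dropped_ppm = dropped),
            class = "preprocess_result")
}

#' Run the full preprocessing pipeline
#'
#' Applies, in the fixed order exclusion -> normalization -> scaling, the
#' steps requested in the configuration, and records every applied factor so
#' the processed matrix is exactly reproducible from the raw one.
#'
#' @param m A [spectra_matrix].
#' @param excluded_regions Regions for [exclude_regions] (`NULL` = none).
#' @param normalization One of `"none"`, `"total_area"`, `"pqn"`.
#' @param area_target Target row sum for the normalization step.
#' @param scaling Scaling method for [scale_variables].
#' @return A `preprocess_result` with `matrix`, `dilution_factors`,
#'   `centers`, `scales`, `dropped_ppm` and the echoed `config`.
#' @export
preprocess <- function(m, excluded_regions = NULL,
                       normalization = c("none", "total_area", "pqn"),
                       area_target = 100,
                       scaling = c("none", "center", "uv", "pareto")) {
  normalization <- match.arg(normalization)
  scaling <- match.arg(scaling)
  cfg <- list(excluded_regions = as_region_matrix(excluded_regions),
              normalization = normalization, area_target = area_target,
              scaling = scaling)
  m1 <- exclude_regions(m, excluded_regions)
  norm <- switch(normalization,
    none = list(matrix = m1,
                dilution_factors = stats::setNames(rep(1, nrow(m1$X)),
                                                   sample_ids(m1))),
    total_area = normalize_total_area(m1, area_target),
    pqn = normalize_pqn(m1, area_target = area_target))
  sc <- scale_variables(norm$matrix, scaling)
  structure(list(matrix = sc$matrix,
                 dilution_factors = norm$dilution_factors,
                 centers = sc$centers, scales = sc$scales,
                 dropped_ppm = sc$dropped_ppm, config = cfg),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat(sprintf("<preprocess_result> %d samples x %d variables\n",
              nrow(x$matrix$X), ncol(x$matrix$X)))
  invisible(x)
}
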