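# Synthetic multi-class 1H-NMR cohort generator with known ground truth:
# compounds as explicit peak lists with Lorentzian lineshapes, per-sample
# log-uniform base concentrations, multiplicative per-class biomarker
# effects, a coherent per-sample chemical-shift jitter, and additive
# Gaussian noise. One seed drives all randomness.

#' Define a compound as a peak list
#'
#' @param name Compound name.
#' @param peaks Two-column matrix (or data frame) of `center_ppm` and
#'   `relative_intensity` (> 0), one row per resonance.
#' @param linewidth_ppm Full width at half maximum of the Lorentzian
#'   lineshape, in ppm.
#' @return A `compound_spec` list.
#' @export
compound_spec <- function(name, peaks, linewidth_ppm = 0.02) {
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 1L || ncol(peaks) != 2L)
    stop("peaks must be a matrix of (center_ppm, relative_intensity) rows")
  if (any(peaks[, 2] <= 0)) stop("relative intensities must be > 0")
  if (linewidth_ppm <= 0) stop("linewidth_ppm must be > 0")
  colnames(peaks) <- c("center_ppm", "relative_intensity")
  structure(list(name = name, peaks = peaks, linewidth_ppm = linewidth_ppm),
            class = "compound_spec")
}

#' Built-in compound library
#'
#' A small library of urine-plausible compound templates (doublets, singlets,
#' multiplets across the usual aliphatic/carbohydrate/aromatic windows) used
#' by the simulator. The peak positions and relative intensities are
#' illustrative fixtures for exercising the pipeline, not curated literature
#' assignments.
#'
#' @return Named list of [compound_spec]s.
#' @export
builtin_library <- function() {
  specs <- list(
    compound_spec("lactate", rbind(c(1.330, 1.00), c(1.346, 0.98),
                                   c(4.110, 0.30), c(4.126, 0.28))),
    compound_spec("alanine", rbind(c(1.470, 1.00), c(1.486, 0.95))),
    compound_spec("acetate", rbind(c(1.920, 1.00))),
    compound_spec("citrate", rbind(c(2.540, 0.90), c(2.660, 1.00))),
    compound_spec("creatinine", rbind(c(3.050, 1.00), c(4.060, 0.55))),
    compound_spec("taurine", rbind(c(3.270, 0.85), c(3.430, 1.00))),
    compound_spec("glycine", rbind(c(3.560, 1.00))),
    compound_spec("glucose", rbind(c(3.250, 0.40), c(3.400, 0.60),
                                   c(3.480, 0.70), c(3.720, 0.80),
                                   c(3.840, 0.55), c(5.230, 1.00))),
    compound_spec("hippurate", rbind(c(3.970, 0.70), c(7.550, 0.60),
                                     c(7.640, 0.80), c(7.840, 1.00)))
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Simulator configuration
#'
#' @param compounds Named list of [compound_spec]s (default:
#'   [builtin_library()]).
#' @param n_classes Number of classes (>= 1).
#' @param n_per_class Samples per class (recycled to `n_classes`).
#' @param biomarkers Named list: compound name -> numeric vector of
#'   per-class mean concentration multipliers (length `n_classes`, all > 0).
#'   Compounds not listed get multiplier 1 in every class.
#' @param conc_range Named list: compound name -> `c(low, high)` bounds of
#'   the log-uniform base concentration (default `c(0.5, 2)` for every
#'   compound, spanning the 4-fold spread typical of urinary metabolites).
#' @param shift_jitter_sd Standard deviation (ppm) of the per-sample global
#'   chemical-shift offset (models coherent pH/ionic-strength shifts).
#' @param noise_sd Standard deviation of the additive Gaussian noise per
#'   grid point, in intensity units.
#' @param grid `c(ppm_hi, ppm_lo, n_points)` of the output grid
#'   (`n_points >= 100`).
#' @param presence_count Optional named list: compound name -> exact number
#'   of samples (chosen at random) in which the compound occurs; all other
#'   samples get concentration 0 for it. Compounds not listed occur in every
#'   sample.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(compounds = builtin_library(), n_classes = 2,
                       n_per_class = 20, biomarkers = list(),
                       conc_range = list(), shift_jitter_sd = 0.001,
                       noise_sd = 0.01, grid = c(9.5, 0.5, 1000),
                       presence_count = list(), seed = 1) {
  stopifnot(n_classes >= 1, length(compounds) >= 1)
  n_per_class <- rep_len(as.integer(n_per_class), n_classes)
  if (any(n_per_class < 1)) stop("n_per_class must be >= 1")
  if (length(grid) != 3L || !(grid[1] > grid[2]) || grid[3] < 100)
    stop("grid must be c(ppm_hi, ppm_lo, n_points) with ppm_hi > ppm_lo and n_points >= 100")
  cn <- names(compounds)
  if (is.null(cn) || any(!nzchar(cn))) stop("compounds must be a named list")
  for (b in names(biomarkers)) {
    if (!b %in% cn) stop("biomarker compound not in library: ", b)
    mult <- biomarkers[[b]]
    if (length(mult) != n_classes || any(mult <= 0))
      stop("biomarker multipliers for ", b, " must be ", n_classes,
           " positive values")
  }
  for (b in names(conc_range)) {
    if (!b %in% cn) stop("conc_range compound not in library: ", b)
    r <- conc_range[[b]]
    if (length(r) != 2L || !(r[1] < r[2]) || r[1] <= 0)
      stop("conc_range for ", b, " must be c(low, high) with 0 < low < high")
  }
  for (b in names(presence_count)) {
    if (!b %in% cn) stop("presence_count compound not in library: ", b)
    if (presence_count[[b]] < 0 || presence_count[[b]] > sum(n_per_class))
      stop("presence_count for ", b, " out of range")
  }
  structure(list(compounds = compounds, n_classes = n_classes,
                 n_per_class = n_per_class, biomarkers = biomarkers,
                 conc_range = conc_range, shift_jitter_sd = shift_jitter_sd,
                 noise_sd = noise_sd, grid = grid,
                 presence_count = presence_count, seed = as.integer(seed)),
            class = "sim_config")
}

# Lorentzian with unit apex: L(v; mu, w) = (w/2)^2 / ((v - mu)^2 + (w/2)^2)
lorentzian <- function(v, mu, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((v - mu)^2 + hw2)
}

#' Generate a synthetic cohort
#'
#' Per sample `i` of class `g` and compound `c`, the concentration is
#' `base_c * multiplier_{g,c}` with `base_c` log-uniform in the compound's
#' range. The spectrum is the concentration-weighted sum of each compound's
#' Lorentzian peaks, all shifted by the sample's jitter offset, plus
#' additive Gaussian noise. Peaks falling outside the grid are truncated
#' with a warning.
#'
#' @param config A [sim_config].
#' @return List of class `sim_dataset`: `matrix` (a [spectra_matrix]),
#'   `annotations` (data frame `sample_id`, `class`, `seed`), `truth`
#'   (per-sample per-compound concentrations), `truth_jitter` (named
#'   per-sample ppm offsets), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$n_per_class)
  classes <- rep(paste0("class", seq_len(config$n_classes)),
                 times = config$n_per_class)
  ids <- sprintf("sample_%03d", seq_len(n))
  ppm <- seq(config$grid[1], config$grid[2], length.out = config$grid[3])
  cn <- names(config$compounds)
  for (nm in cn) {
    centers <- config$compounds[[nm]]$peaks[, 1]
    if (any(centers > config$grid[1] | centers < config$grid[2]))
      warning(sprintf("compound '%s' has peak(s) outside the grid; tails truncated", nm))
  }
  conc <- matrix(0, n, length(cn), dimnames = list(ids, cn))
  jitter <- numeric(n)
  noise <- matrix(0, n, length(ppm))
  with_seed(config$seed, {
    for (j in seq_along(cn)) {
      r <- config$conc_range[[cn[j]]] %||% c(0.5, 2)
      conc[, j] <- exp(stats::runif(n, log(r[1]), log(r[2])))
    }
    for (nm in names(config$presence_count)) {
      absent <- setdiff(seq_len(n), sample(n, config$presence_count[[nm]]))
      conc[absent, nm] <- 0
    }
    for (nm in names(config$biomarkers)) {
      mult <- config$biomarkers[[nm]]
      conc[, nm] <- conc[, nm] * mult[match(classes, paste0("class", seq_len(config$n_classes)))]
    }
    jitter <- stats::rnorm(n, 0, config$shift_jitter_sd)
    if (config$noise_sd > 0)
      noise <- matrix(stats::rnorm(n * length(ppm), 0, config$noise_sd),
                      n, length(ppm))
  })
  X <- matrix(0, n, length(ppm))
  for (j in seq_along(cn)) {
    pk <- config$compounds[[cn[j]]]$peaks
    fwhm <- config$compounds[[cn[j]]]$linewidth_ppm
    active <- which(conc[, j] > 0)
    if (length(active) == 0) next
    for (k in seq_len(nrow(pk))) {
      for (i in active) {
        X[i, ] <- X[i, ] + conc[i, j] * pk[k, 2] *
          lorentzian(ppm, pk[k, 1] + jitter[i], fwhm)
      }
    }
  }
  X <- X + noise
  truth <- data.frame(sample_id = ids, class = classes,
                      as.data.frame(conc, row.names = NULL),
                      check.names = FALSE)
  annotations <- data.frame(sample_id = ids, class = classes,
                            seed = as.character(config$seed),
                            stringsAsFactors = FALSE)
  structure(list(matrix = spectra_matrix(X, ppm, ids),
                 annotations = annotations, truth = truth,
                 truth_jitter = stats::setNames(jitter, ids),
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d samples (%d classes) x %d variables, seed %d\n",
              nrow(x$matrix$X), x$config$n_classes, ncol(x$matrix$X),
              x$config$seed))
  invisible(x)
}

#' Tallest-peak ppm of a compound
#'
#' Convenience accessor: the center of the peak with the largest relative
#' intensity (ground truth for loading-recovery checks).
#' @param compound A [compound_spec].
#' @return The apex ppm.
#' @export
tallest_peak <- function(compound) {
  compound$peaks[which.max(compound$peaks[, 2]), 1]
}
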