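# NIPALS principal components analysis with Hotelling T-squared outlier
# limits and the iterative exclude/refit/re-project workflow.

#' Fit a PCA model by NIPALS
#'
#' Nonlinear iterative partial least squares: for each component the score
#' vector is initialized with the column of maximal variance, then
#' `p = X't/(t't)` (normalized) and `t = X p` are alternated until the
#' relative change of the score vector falls below `tol`; the component is
#' deflated (`X <- X - t p'`) before the next one. Loading signs are fixed so
#' that the entry of largest magnitude is positive. Explained variance per
#' component is `t't` over the total sum of squares of the (centered/scaled)
#' matrix.
#'
#' @param m A [spectra_matrix].
#' @param n_components Number of components, at most `min(n - 1, p)` when
#'   centering (`min(n, p)` otherwise).
#' @param center Mean-center columns before fitting (default TRUE). Centers
#'   are stored in the model and applied again on projection.
#' @param scale Per-variable scaling applied before fitting: `"none"`,
#'   `"uv"` or `"pareto"`.
#' @param tol Convergence tolerance on the relative score change.
#' @param max_iter Maximum NIPALS iterations per component; non-convergence
#'   yields a warning and the best iterate.
#' @return An object of class `pca_model`: `loadings` (p x A, orthonormal
#'   columns), `scores` (n x A), `explained_variance_ratio`, `centers`,
#'   `scales`, `ppm`, `sample_ids`, `total_ss`.
#' @export
fit_pca <- function(m, n_components = 2, center = TRUE,
                    scale = c("none", "uv", "pareto"),
                    tol = 1e-13, max_iter = 100000) {
  scale <- match.arg(scale)
  X <- m$X
  n <- nrow(X); p <- ncol(X)
  a_max <- min(if (center) n - 1L else n, p)
  if (n_components > a_max)
    stop(sprintf("n_components = %d exceeds maximum %d for %d x %d data",
                 n_components, a_max, n, p))
  centers <- if (center) colMeans(X) else rep(0, p)
  scales <- rep(1, p)
  if (scale != "none") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance column under ", scale,
                            " scaling; drop it first (see scale_variables)")
    scales <- if (scale == "uv") sds else sqrt(sds)
  }
  Xw <- sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
  total_ss <- sum(Xw^2)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  Xr <- Xw
  for (a in seq_len(n_components)) {
    nip <- nipals_component(Xr, tol, max_iter)
    t_a <- nip$t; p_a <- nip$p
    # sign convention: largest-|loading| entry positive
    s <- sign(p_a[which.max(abs(p_a))])
    if (s < 0) { p_a <- -p_a; t_a <- -t_a }
    P[, a] <- p_a
    Tm[, a] <- t_a
    Xr <- Xr - tcrossprod(t_a, p_a)
  }
  evr <- colSums(Tm^2) / total_ss
  structure(list(loadings = P, scores = Tm,
                 explained_variance_ratio = evr,
                 centers = centers, scales = scales,
                 ppm = m$ppm, sample_ids = sample_ids(m),
                 total_ss = total_ss, residual_ss = sum(Xr^2),
                 n_components = n_components),
            class = "pca_model")
}

# one NIPALS component on an (already centered/deflated) matrix
nipals_component <- function(X, tol, max_iter) {
  j0 <- which.max(apply(X, 2, function(x) sum(x^2)))
  t_a <- X[, j0]
  if (sum(t_a^2) == 0) stop("NIPALS: residual matrix is zero (rank exhausted)")
  converged <- FALSE
  p_a <- NULL
  for (it in seq_len(max_iter)) {
    p_a <- crossprod(X, t_a) / sum(t_a^2)
    p_a <- p_a / sqrt(sum(p_a^2))
    t_new <- X %*% p_a
    delta <- sqrt(sum((t_new - t_a)^2)) / sqrt(sum(t_new^2))
    t_a <- drop(t_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("NIPALS did not converge in %d iterations (last delta %.3g); returning best iterate",
                    max_iter, delta))
  list(t = t_a, p = drop(p_a))
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, %d samples x %d variables\n",
              x$n_components, length(x$sample_ids), length(x$ppm)))
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Project samples into a fitted PCA model
#'
#' Applies the model's stored centers and scales, then computes scores as
#' `T_new = X_new P`. Projecting the training matrix reproduces the training
#' scores.
#'
#' @param model A `pca_model`.
#' @param m A [spectra_matrix] on the same ppm grid as the training data.
#' @return Numeric score matrix (rows = samples of `m`, columns = components).
#' @export
project_pca <- function(model, m) {
  check_same_grid(model$ppm, m$ppm)
  Xw <- sweep(sweep(m$X, 2, model$centers, "-"), 2, model$scales, "/")
  scores <- Xw %*% model$loadings
  rownames(scores) <- sample_ids(m)
  scores
}

#' Hotelling T-squared outlier report
#'
#' Per-sample `T2_i = sum_a t_ia^2 / lambda_a` with `lambda_a` the
#' per-component score variance (n-1 denominator). The confidence limit is
#' the standard chemometrics ellipse bound
#' `A (n-1)(n+1) / (n (n-A)) * F(1-alpha; A, n-A)`; samples with `T2` above
#' the limit are flagged.
#'
#' @param model A `pca_model` with `n > n_components`.
#' @param alpha Significance level of the limit (default 0.05).
#' @return List of class `outlier_report`: `t2` (named per-sample), `limit`,
#'   `alpha`, `flagged` (sample ids with `t2 > limit`).
#' @export
hotelling_outliers <- function(model, alpha = 0.05) {
  Tm <- model$scores
  n <- nrow(Tm); A <- ncol(Tm)
  if (n <= A) stop("Hotelling T2 requires more samples than components")
  lambda <- apply(Tm, 2, stats::var)
  t2 <- rowSums(sweep(Tm^2, 2, lambda, "/"))
  names(t2) <- model$sample_ids
  limit <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(1 - alpha, A, n - A)
  structure(list(t2 = t2, limit = limit, alpha = alpha,
                 flagged = names(t2)[t2 > limit]),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> limit %.3f (alpha %.3g): %d flagged\n",
              x$limit, x$alpha, length(x$flagged)))
  if (length(x$flagged)) cat(" ", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Refit a PCA model after excluding samples, re-projecting the excluded ones
#'
#' The interactive outlier workflow: remove the chosen samples, refit the
#' model on the retained rows (re-centered), then project the excluded
#' samples back into the new model to judge the impact of their removal.
#'
#' @param m A [spectra_matrix].
#' @param excluded_ids Sample ids to exclude (may be empty).
#' @param ... Arguments passed to [fit_pca] (`n_components`, `center`, ...).
#' @return List with `model` (the refitted `pca_model`) and
#'   `excluded_scores` (projection of the excluded samples; 0-row matrix if
#'   none excluded).
#' @export
refit_excluding <- function(m, excluded_ids = character(0), ...) {
  unknown <- setdiff(excluded_ids, sample_ids(m))
  if (length(unknown) > 0)
    stop("excluded ids not in matrix: ", paste(unknown, collapse = ", "))
  keep <- setdiff(sample_ids(m), excluded_ids)
  args <- list(...)
  ncomp <- args$n_components %||% 2
  if (length(keep) < ncomp + 1L)
    stop(sprintf("only %d samples would remain; need at least %d",
                 length(keep), ncomp + 1L))
  m_keep <- subset_samples(m, keep)
  model <- fit_pca(m_keep, ...)
  excluded_scores <- if (length(excluded_ids) > 0) {
    project_pca(model, subset_samples(m, excluded_ids))
  } else {
    matrix(numeric(0), nrow = 0, ncol = model$n_components)
  }
  list(model = model, excluded_scores = excluded_scores)
}
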