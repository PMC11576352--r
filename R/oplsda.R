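# Two-class OPLS-DA: one predictive component plus k orthogonal components,
# test-set prediction, stratified cross-validated Q2, and the
# predictive-vs-orthogonal loading decomposition.

# code class labels as -1/+1: the lexicographically larger label is +1
code_y <- function(classes) {
  lv <- sort(unique(as.character(classes)))
  if (length(lv) != 2L)
    stop("OPLS-DA needs exactly two classes, got: ", paste(lv, collapse = ", "))
  y <- ifelse(as.character(classes) == lv[2], 1, -1)
  list(y = y, class_labels = lv)  # lv[1] -> -1, lv[2] -> +1
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis. The
#' class vector is coded -1/+1. For each of the `n_orth` orthogonal
#' components: `w = X'y/(y'y)` (normalized), `t = Xw`, `p = X't/(t't)`,
#' `w_o = p - (w'p) w` (normalized), `t_o = X w_o`, `p_o = X't_o/(t_o't_o)`,
#' and `X <- X - t_o p_o'`. The single predictive component is then computed
#' on the deflated matrix: `t_pred = X w`, `p_pred = X't_pred/(t_pred't_pred)`
#' and the y-loading `q = y't_pred/(t_pred't_pred)`. With `n_orth = 0` the
#' model reduces exactly to the first PLS1 component.
#'
#' Centering (and optional scaling) is applied internally and stored so test
#' sets can be mapped through [predict_oplsda] untouched.
#'
#' @param m A [spectra_matrix].
#' @param classes Class label per sample (character/factor, exactly 2 levels).
#' @param n_orth Number of orthogonal components (default 1).
#' @param center Mean-center columns (default TRUE).
#' @param scale `"none"`, `"uv"` or `"pareto"` column scaling.
#' @return An object of class `oplsda_model` with weights/loadings/scores of
#'   the predictive (`w`, `p_pred`, `t_pred`, `q`) and orthogonal (`W_o`,
#'   `P_o`, `T_o`) parts, the stored `centers`/`scales`, `class_labels`
#'   (first label coded -1, second +1), `y_mean`, and the variance fractions
#'   `r2x_pred`, `r2x_orth`, `r2y`.
#' @export
fit_oplsda <- function(m, classes, n_orth = 1, center = TRUE,
                       scale = c("none", "uv", "pareto")) {
  scale <- match.arg(scale)
  cy <- code_y(classes)
  y <- cy$y
  X <- m$X
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("one class label per sample required")
  centers <- if (center) colMeans(X) else rep(0, p)
  scales <- rep(1, p)
  if (scale != "none") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance column under ", scale, " scaling")
    scales <- if (scale == "uv") sds else sqrt(sds)
  }
  Xw <- sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
  ssx <- sum(Xw^2)
  ssy <- sum(y^2)
  W_o <- matrix(0, p, n_orth)
  P_o <- matrix(0, p, n_orth)
  T_o <- matrix(0, n, n_orth)
  Xr <- Xw
  for (j in seq_len(n_orth)) {
    w <- drop(crossprod(Xr, y)) / ssy
    wn <- sqrt(sum(w^2))
    if (wn == 0) stop("X carries no y-covariance; cannot extract component ", j)
    w <- w / wn
    t_ <- drop(Xr %*% w)
    p_ <- drop(crossprod(Xr, t_)) / sum(t_^2)
    w_o <- p_ - sum(w * p_) * w
    won <- sqrt(sum(w_o^2))
    if (won < 1e-12)
      stop(sprintf("no orthogonal variation left for component %d (n_orth too large for rank)", j))
    w_o <- w_o / won
    t_o <- drop(Xr %*% w_o)
    p_o <- drop(crossprod(Xr, t_o)) / sum(t_o^2)
    W_o[, j] <- w_o; P_o[, j] <- p_o; T_o[, j] <- t_o
    Xr <- Xr - tcrossprod(t_o, p_o)
  }
  w <- drop(crossprod(Xr, y)) / ssy
  wn <- sqrt(sum(w^2))
  if (wn == 0) stop("X carries no y-covariance; cannot extract predictive component")
  w <- w / wn
  t_pred <- drop(Xr %*% w)
  p_pred <- drop(crossprod(Xr, t_pred)) / sum(t_pred^2)
  q <- sum(y * t_pred) / sum(t_pred^2)
  r2y <- 1 - sum((y - q * t_pred)^2) / ssy
  E <- Xr - tcrossprod(t_pred, p_pred)
  structure(list(class_labels = cy$class_labels, y = y, y_mean = mean(y),
                 w = w, p_pred = p_pred, t_pred = t_pred, q = q,
                 W_o = W_o, P_o = P_o, T_o = T_o, n_orth = n_orth,
                 centers = centers, scales = scales,
                 ppm = m$ppm, sample_ids = sample_ids(m),
                 r2x_pred = sum(t_pred^2) * sum(p_pred^2) / ssx,
                 r2x_orth = if (n_orth > 0)
                   sum(colSums(T_o^2) * colSums(P_o^2)) / ssx else 0,
                 r2x_residual = sum(E^2) / ssx,
                 r2y = r2y),
            class = "oplsda_model")
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("<oplsda_model> %s (-1) vs %s (+1), %d orthogonal component(s)\n",
              x$class_labels[1], x$class_labels[2], x$n_orth))
  cat(sprintf("R2X(pred) %.3f  R2X(orth) %.3f  R2Y %.3f\n",
              x$r2x_pred, x$r2x_orth, x$r2y))
  invisible(x)
}

#' Predict class membership for new samples
#'
#' Maps a test set through a fitted OPLS-DA model: the stored centers/scales
#' are applied, each orthogonal component is removed in fit order
#' (`t_o = x W_o[,j]`; `x <- x - t_o P_o[,j]'`), then the predictive score
#' `t_pred = x w` and `y_hat = q t_pred` are computed. Class is assigned by
#' the sign of `y_hat`; an exact tie (`y_hat == 0`) takes the
#' lexicographically first label.
#'
#' @param model An `oplsda_model`.
#' @param m A [spectra_matrix] on the model's ppm grid.
#' @return List of class `oplsda_prediction`: `t_pred`, `t_orth` (n x
#'   n_orth), `y_hat`, `predicted_class` (all named/rowed by sample id).
#' @export
predict_oplsda <- function(model, m) {
  check_same_grid(model$ppm, m$ppm)
  Xn <- sweep(sweep(m$X, 2, model$centers, "-"), 2, model$scales, "/")
  t_orth <- matrix(0, nrow(Xn), model$n_orth)
  for (j in seq_len(model$n_orth)) {
    t_o <- drop(Xn %*% model$W_o[, j])
    Xn <- Xn - tcrossprod(t_o, model$P_o[, j])
    t_orth[, j] <- t_o
  }
  t_pred <- drop(Xn %*% model$w)
  y_hat <- model$q * t_pred
  cls <- ifelse(y_hat > 0, model$class_labels[2], model$class_labels[1])
  ids <- sample_ids(m)
  rownames(t_orth) <- ids
  structure(list(t_pred = stats::setNames(t_pred, ids), t_orth = t_orth,
                 y_hat = stats::setNames(y_hat, ids),
                 predicted_class = stats::setNames(cls, ids)),
            class = "oplsda_prediction")
}

#' @export
print.oplsda_prediction <- function(x, ...) {
  cat(sprintf("<oplsda_prediction> %d samples: %s\n", length(x$y_hat),
              paste(sprintf("%s=%d", names(table(x$predicted_class)),
                            as.integer(table(x$predicted_class))),
                    collapse = ", ")))
  invisible(x)
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Stratified k-fold cross-validation: within each class the samples are
#' shuffled (seeded) and dealt round-robin into folds, so every fold contains
#' both classes whenever `folds <= min(class size)`. For each fold the model
#' is refit on the remaining samples and the held-out `y` is predicted;
#' `Q2 = 1 - PRESS / SS_y` with `SS_y = sum(y^2)` for the -1/+1 coding.
#'
#' @param m A [spectra_matrix].
#' @param classes Class label per sample (2 levels).
#' @param n_orth Orthogonal components per fold model.
#' @param folds Number of folds (default 7, chemometrics convention).
#' @param seed Integer seed making the fold assignment deterministic.
#' @param ... Passed to [fit_oplsda] (`center`, `scale`).
#' @return List with `q2`, `press`, `ss_y`, `y_hat` (cross-validated
#'   predictions in sample order) and `fold` assignments.
#' @export
cross_validate_oplsda <- function(m, classes, n_orth = 1, folds = 7, seed = 1,
                                  ...) {
  if (folds < 2) stop("folds must be >= 2")
  cy <- code_y(classes)
  y <- cy$y
  n <- nrow(m$X)
  cls <- as.character(classes)
  if (min(table(cls)) < folds)
    stop(sprintf("folds = %d exceeds smallest class size %d; every fold must see both classes",
                 folds, min(table(cls))))
  fold <- integer(n)
  with_seed(seed, {
    for (lv in unique(cls)) {
      idx <- sample(which(cls == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  y_hat <- numeric(n)
  ids <- sample_ids(m)
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- fit_oplsda(subset_samples(m, ids[!test]), cls[!test],
                      n_orth = n_orth, ...)
    pred <- predict_oplsda(fit, subset_samples(m, ids[test]))
    y_hat[test] <- pred$y_hat
  }
  press <- sum((y - y_hat)^2)
  ss_y <- sum(y^2)
  list(q2 = 1 - press / ss_y, press = press, ss_y = ss_y,
       y_hat = stats::setNames(y_hat, ids), fold = stats::setNames(fold, ids))
}

#' Predictive vs orthogonal loading decomposition
#'
#' Tabulates, per chemical-shift variable, the predictive loading, each
#' orthogonal loading, and the rank of the variable by `|p_pred|` (rank 1 =
#' largest magnitude). This is the table used to read which signals drive the
#' class separation and which carry structured y-orthogonal variation.
#'
#' @param model An `oplsda_model`.
#' @return Data frame with columns `ppm`, `p_pred`, `p_orth_1..k` (absent if
#'   `n_orth = 0`) and `rank`.
#' @export
loading_decomposition <- function(model) {
  df <- data.frame(ppm = model$ppm, p_pred = model$p_pred)
  for (j in seq_len(model$n_orth))
    df[[paste0("p_orth_", j)]] <- model$P_o[, j]
  df$rank <- rank(-abs(model$p_pred), ties.method = "first")
  df
}

# run code with a temporary RNG state; restores (or removes) .Random.seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
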