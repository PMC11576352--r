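# OPLS-DA: PLS1 reduction, orthogonal filtering, prediction, Q2, loadings.

make_xy <- function(n = 24, p = 40, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  cls <- rep(c("A", "B"), each = n / 2)
  m <- spectra_matrix(X, seq(9, 1, length.out = p))
  list(m = m, cls = cls, y = ifelse(cls == "B", 1, -1))
}

test_that("with zero orthogonal components the model is PLS1's first component", {
  d <- make_xy(seed = 3)
  fit <- fit_oplsda(d$m, d$cls, n_orth = 0)
  # direct PLS1 oracle on the centered matrix
  Xc <- scale(d$m$X, center = TRUE, scale = FALSE)
  w <- drop(crossprod(Xc, d$y)); w <- w / sqrt(sum(w^2))
  t_ <- drop(Xc %*% w)
  q <- sum(d$y * t_) / sum(t_^2)
  expect_lt(max(abs(fit$w - w)), 1e-10)
  expect_lt(max(abs(fit$t_pred - t_)), 1e-10)
  expect_equal(fit$q, q, tolerance = 1e-10)
})

test_that("one orthogonal component recovers a constructed y-orthogonal trend", {
  set.seed(6)
  n <- 40; p <- 60
  axis_a <- stats::rnorm(p); axis_a <- axis_a / sqrt(sum(axis_a^2))
  axis_b <- stats::rnorm(p)
  axis_b <- axis_b - sum(axis_b * axis_a) * axis_a
  axis_b <- axis_b / sqrt(sum(axis_b^2))
  y <- rep(c(-1, 1), each = n / 2)
  trend <- stats::rnorm(n, sd = 6)       # strong y-orthogonal factor
  trend <- trend - mean(trend)
  trend <- trend - y * sum(trend * y) / sum(y^2)  # make exactly y-orthogonal
  X <- outer(y, axis_a) + outer(trend, axis_b) +
    matrix(stats::rnorm(n * p, sd = 0.01), n, p)
  m <- spectra_matrix(X, seq(9, 1, length.out = p))
  fit <- fit_oplsda(m, ifelse(y > 0, "case", "control"), n_orth = 1)
  cosine <- abs(sum(fit$W_o[, 1] * axis_b))
  expect_gt(cosine, 0.99)
})

test_that("orthogonal scores are uncorrelated with y and with t_pred", {
  for (seed in 1:5) {
    d <- make_xy(seed = seed)
    fit <- fit_oplsda(d$m, d$cls, n_orth = 2)
    for (j in 1:2) {
      expect_lt(abs(stats::cor(fit$T_o[, j], d$y)), 1e-8)
      expect_lt(abs(sum(fit$t_pred * fit$T_o[, j])) /
                  (sqrt(sum(fit$t_pred^2)) * sqrt(sum(fit$T_o[, j]^2))), 1e-8)
    }
    expect_equal(fit$r2x_pred + fit$r2x_orth + fit$r2x_residual, 1,
                 tolerance = 1e-8)
    expect_true(fit$r2y >= 0 && fit$r2y <= 1)
    expect_equal(sqrt(sum(fit$w^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(colSums(fit$W_o^2)), rep(1, 2), tolerance = 1e-12)
  }
})

test_that("prediction is self-consistent and thresholds at zero", {
  d <- make_xy(seed = 8)
  fit <- fit_oplsda(d$m, d$cls, n_orth = 1)
  pred <- predict_oplsda(fit, d$m)
  expect_lt(max(abs(unname(pred$t_pred) - fit$t_pred)), 1e-8)

  # the mean spectrum is zero after centering: y_hat 0, tie -> first label
  mean_m <- spectra_matrix(matrix(colMeans(d$m$X), 1), d$m$ppm, "mean")
  pm <- predict_oplsda(fit, mean_m)
  expect_equal(unname(pm$y_hat), 0, tolerance = 1e-12)
  expect_equal(unname(pm$predicted_class), "A")
})

test_that("a separable simulated cohort is classified perfectly out of sample", {
  ds <- small_cohort(seed = 101, n_per_class = 60, multiplier = 3,
                     noise_sd = 0.02, shift_jitter_sd = 0.001)
  ids <- sample_ids(ds$matrix)
  cls <- ds$annotations$class
  train <- c(ids[cls == "class1"][1:40], ids[cls == "class2"][1:40])
  test <- setdiff(ids, train)
  fit <- fit_oplsda(subset_samples(ds$matrix, train),
                    cls[match(train, ids)], n_orth = 1)
  pred <- predict_oplsda(fit, subset_samples(ds$matrix, test))
  expect_equal(mean(pred$predicted_class == cls[match(test, ids)]), 1)
})

test_that("Q2 behaves: high for predictable y, near zero under permutation", {
  set.seed(31)
  n <- 28; p <- 30
  y <- rep(c(-1, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * p, sd = 0.05), n, p)
  X[, 1] <- y  # y duplicated as a column, little variance elsewhere
  m <- spectra_matrix(X, seq(9, 1, length.out = p))
  cls <- ifelse(y > 0, "B", "A")
  cv <- cross_validate_oplsda(m, cls, n_orth = 0, folds = 7, seed = 5)
  expect_gt(cv$q2, 0.99)
  expect_equal(cv, cross_validate_oplsda(m, cls, n_orth = 0, folds = 7, seed = 5))

  fit <- fit_oplsda(m, cls, n_orth = 0)
  expect_lte(cv$q2, fit$r2y + 1e-12)

  q2_null <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    cross_validate_oplsda(m, sample(cls), n_orth = 0, folds = 7,
                          seed = i)$q2
  }, numeric(1))
  expect_lt(mean(q2_null), 0.1)
})

test_that("loading decomposition ranks the biomarker apex first", {
  ds <- small_cohort(seed = 77, n_per_class = 30, multiplier = 3,
                     noise_sd = 0.01)
  fit <- fit_oplsda(ds$matrix, ds$annotations$class, n_orth = 1)
  tab <- loading_decomposition(fit)
  expect_equal(nrow(tab), ncol(ds$matrix$X))
  apex <- tallest_peak(builtin_library()$glycine)
  top <- tab$ppm[tab$rank == 1]
  grid_step <- abs(diff(ds$matrix$ppm[1:2]))
  expect_lt(abs(top - apex), 2.5 * grid_step)

  tab0 <- loading_decomposition(fit_oplsda(ds$matrix, ds$annotations$class,
                                           n_orth = 0))
  expect_false(any(grepl("p_orth", names(tab0))))
})

test_that("degenerate inputs are rejected", {
  d <- make_xy(seed = 2)
  expect_error(fit_oplsda(d$m, rep("A", 24)), "two classes")
  expect_error(cross_validate_oplsda(d$m, d$cls, folds = 13, seed = 1),
               "class size")
})
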