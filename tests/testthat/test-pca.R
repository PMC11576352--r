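# NIPALS PCA: oracle equivalence, projection, Hotelling T2, exclude/refit.

test_that("a rank-1 matrix is fully explained by one component", {
  set.seed(2)
  t0 <- stats::rnorm(15)
  p0 <- stats::rnorm(40)
  m <- spectra_matrix(outer(t0, p0), seq(9, 1, length.out = 40))
  fit <- fit_pca(m, 1, center = FALSE)
  expect_equal(fit$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_lt(sqrt(fit$residual_ss), 1e-10)
})

test_that("NIPALS matches the truncated SVD oracle on random matrices", {
  for (seed in 1:10) {
    m <- rand_matrix(20, 50, seed = seed)
    fit <- fit_pca(m, 4)
    oracle <- svd_pca_oracle(m$X, 4)
    expect_lt(max(abs(fit$scores - oracle$scores)), 1e-8)
    expect_lt(max(abs(fit$loadings - oracle$loadings)), 1e-8)
  }
})

test_that("explained variance sums to 1 at full rank and deflation conserves SS", {
  m <- rand_matrix(8, 30, seed = 4)
  fit <- fit_pca(m, 7)  # rank of a centered 8 x 30 matrix
  expect_equal(sum(fit$explained_variance_ratio), 1, tolerance = 1e-10)

  m2 <- rand_matrix(20, 50, seed = 5)
  f2 <- fit_pca(m2, 3)
  expect_equal(sum(colSums(f2$scores^2)) + f2$residual_ss, f2$total_ss,
               tolerance = 1e-8 * f2$total_ss)
})

test_that("model invariants hold: orthonormal loadings, orthogonal scores", {
  fit <- fit_pca(rand_matrix(25, 60, seed = 7), 5)
  G <- crossprod(fit$loadings)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  S <- crossprod(fit$scores)
  expect_lt(max(abs(S - diag(diag(S)))) / max(diag(S)), 1e-8)
  expect_true(all(diff(fit$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(fit$explained_variance_ratio), 1 + 1e-12)
})

test_that("projection reproduces training scores and is linear", {
  m <- rand_matrix(18, 40, seed = 9)
  fit <- fit_pca(m, 3)
  expect_lt(max(abs(project_pca(fit, m) - fit$scores)), 1e-8)

  # the mean spectrum projects to the origin
  mean_m <- spectra_matrix(matrix(colMeans(m$X), 1), m$ppm, "mean")
  expect_lt(max(abs(project_pca(fit, mean_m))), 1e-10)

  # linearity on centered inputs
  c1 <- m$X[1, ] - colMeans(m$X)
  c2 <- m$X[2, ] - colMeans(m$X)
  combo <- spectra_matrix(rbind(2 * c1 + 3 * c2) + rep(colMeans(m$X), each = 1),
                          m$ppm, "combo")
  expect_equal(drop(project_pca(fit, combo)),
               drop(2 * (c1 %*% fit$loadings) + 3 * (c2 %*% fit$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)

  wrong <- spectra_matrix(m$X, m$ppm + 0.1, sample_ids(m))
  expect_error(project_pca(fit, wrong), "mismatch")
})

test_that("Hotelling T2 matches the direct formula and flags a gross outlier", {
  set.seed(12)
  X <- matrix(stats::rnorm(30 * 20), 30, 20)
  X[7, ] <- X[7, ] + 12   # gross outlier
  m <- spectra_matrix(X, seq(8, 1, length.out = 20))
  fit <- fit_pca(m, 2)
  rep_ <- hotelling_outliers(fit, alpha = 0.05)
  expect_true("S7" %in% rep_$flagged)

  # direct formula oracle
  lam <- apply(fit$scores, 2, stats::var)
  t2_oracle <- fit$scores[, 1]^2 / lam[1] + fit$scores[, 2]^2 / lam[2]
  expect_lt(max(abs(unname(rep_$t2) - t2_oracle)), 1e-10)
  n <- 30; A <- 2
  lim_oracle <- A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(0.95, A, n - A)
  expect_equal(rep_$limit, lim_oracle, tolerance = 1e-12)

  # alpha -> 1: zero limit, everything flagged
  all_rep <- hotelling_outliers(fit, alpha = 1)
  expect_equal(all_rep$limit, 0)
  expect_equal(length(all_rep$flagged), n)

  expect_error(hotelling_outliers(fit_pca(rand_matrix(4, 10, 1), 4,
                                          center = FALSE), 0.05),
               "more samples")
})

test_that("exclude/refit/re-project workflow behaves as a manual composition", {
  set.seed(14)
  X <- matrix(stats::rnorm(25 * 30), 25, 30)
  X[3, ] <- X[3, ] + 10
  m <- spectra_matrix(X, seq(9, 2, length.out = 30))

  same <- refit_excluding(m, character(0), n_components = 2)
  full <- fit_pca(m, n_components = 2)
  expect_equal(same$model$scores, full$scores, tolerance = 1e-10)

  rf <- refit_excluding(m, "S3", n_components = 2)
  # removing the gross outlier shrinks component-1 score variance
  expect_lt(stats::var(rf$model$scores[, 1]), stats::var(full$scores[, 1]))
  # re-projected scores equal project_pca applied manually
  expect_equal(rf$excluded_scores,
               project_pca(rf$model, subset_samples(m, "S3")),
               tolerance = 1e-12)
  # ... and the brute-force centered matrix product
  xc <- (m$X["S3", ] - rf$model$centers) / rf$model$scales
  expect_equal(drop(rf$excluded_scores), drop(xc %*% rf$model$loadings),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(refit_excluding(m, "nope", n_components = 2), "nope")
  expect_error(refit_excluding(rand_matrix(4, 10, 1), c("S001", "S002"),
                               n_components = 3), "remain")
})
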