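# Region exclusion, normalization (total area, PQN) and variable scaling.

test_that("exclude_regions removes exactly the columns inside the intervals", {
  m <- spectra_matrix(matrix(1, 2, 11), seq(10, 0, by = -1))
  out <- exclude_regions(m, cbind(5.0, 4.0))
  expect_equal(ncol(out$X), 9)
  expect_false(any(out$ppm %in% c(4, 5)))
  expect_identical(exclude_regions(m, NULL), m)
  expect_error(exclude_regions(m, cbind(11, -1)), "survive")
})

test_that("exclude_regions agrees with a per-column membership oracle", {
  set.seed(5)
  m <- rand_matrix(3, 80)
  for (rep in 1:10) {
    k <- sample(1:3, 1)
    lo <- stats::runif(k, 0, 9)
    regions <- cbind(lo + stats::runif(k, 0.1, 1), lo)
    keep_oracle <- vapply(m$ppm, function(v)
      !any(v >= regions[, 2] & v <= regions[, 1]), logical(1))
    if (!any(keep_oracle)) next
    out <- exclude_regions(m, regions)
    expect_identical(out$ppm, m$ppm[keep_oracle])
    expect_identical(out$X, m$X[, keep_oracle, drop = FALSE])
  }
})

test_that("total-area normalization conserves the target row sum", {
  m <- spectra_matrix(matrix(c(1, 2, 3), 1, 3), c(3, 2, 1), "s1")
  r <- normalize_total_area(m, 1)
  expect_equal(r$matrix$X[1, ], c(1, 2, 3) / 6)
  expect_equal(unname(r$dilution_factors), 6)

  # already at target: identity with factor 1
  r2 <- normalize_total_area(r$matrix, 1)
  expect_equal(r2$matrix$X, r$matrix$X)
  expect_equal(unname(r2$dilution_factors), 1)

  big <- simulate_dataset(sim_config(n_per_class = 25, grid = c(9.5, 0.5, 500),
                                     seed = 4))$matrix
  rb <- normalize_total_area(big, 100)
  expect_lt(max(abs(rowSums(rb$matrix$X) - 100)), 1e-9)

  bad <- spectra_matrix(matrix(c(1, 1, -2, 0), 2, 2, byrow = TRUE),
                        c(2, 1), c("ok", "neg"))
  expect_error(normalize_total_area(bad), "neg")
})

test_that("PQN recovers constructed dilution factors", {
  set.seed(17)
  profile <- abs(stats::rnorm(50)) + 0.5
  k <- c(1, 0.5, 2, 1.7, 0.8, 1.2)
  X <- outer(k, profile)
  m <- spectra_matrix(X, seq(9, 1, length.out = 50))
  r <- normalize_pqn(m)
  # identical rows after normalization; factor ratios match the k ratios
  expect_lt(max(abs(sweep(r$matrix$X, 2, r$matrix$X[1, ]))), 1e-9)
  fr <- r$dilution_factors / r$dilution_factors[1]
  expect_equal(unname(fr), k / k[1], tolerance = 1e-9)

  # two identical rows: quotients 1, matrix unchanged by the PQN step
  m2 <- spectra_matrix(rbind(profile, profile), seq(9, 1, length.out = 50),
                       c("a", "b"))
  r2 <- normalize_pqn(m2, area_target = sum(profile))
  expect_equal(unname(r2$pqn_quotients), c(1, 1), tolerance = 1e-12)
  expect_equal(r2$matrix$X, m2$X, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PQN recovers simulated dilutions (log-factor correlation > 0.99)", {
  # low compositional variance: the regime PQN assumes, where almost all
  # intensity variation between samples is dilution
  narrow <- stats::setNames(rep(list(c(0.9, 1.11)), 9),
                            names(builtin_library()))
  ds <- simulate_dataset(sim_config(n_per_class = 30, noise_sd = 0,
                                    shift_jitter_sd = 0, conc_range = narrow,
                                    grid = c(9.5, 0.5, 500), seed = 8))
  set.seed(21)
  dil <- exp(stats::runif(nrow(ds$matrix$X), log(0.5), log(2)))
  m <- spectra_matrix(ds$matrix$X * dil, ds$matrix$ppm, sample_ids(ds$matrix))
  r <- normalize_pqn(m)
  expect_gt(stats::cor(log(dil), log(unname(r$dilution_factors))), 0.99)
})

test_that("PQN factors are invariant to a global intensity constant", {
  m <- rand_matrix(8, 60, seed = 13, positive = TRUE)
  q1 <- normalize_pqn(m)$pqn_quotients
  m2 <- spectra_matrix(m$X * 37, m$ppm, sample_ids(m))
  q2 <- normalize_pqn(m2)$pqn_quotients
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("scaling follows the center/uv/pareto definitions (n-1 sd)", {
  m <- spectra_matrix(matrix(c(1, 2, 3), 3, 1), 5, c("a", "b", "c"))
  expect_equal(scale_variables(m, "center")$matrix$X[, 1], c(-1, 0, 1),
               ignore_attr = TRUE)

  r <- rand_matrix(10, 20, seed = 6)
  uv <- scale_variables(r, "uv")
  expect_lt(max(abs(apply(uv$matrix$X, 2, stats::sd) - 1)), 1e-12)

  pa <- scale_variables(r, "pareto")
  sd_orig <- apply(r$X, 2, stats::sd)
  expect_lt(max(abs(apply(pa$matrix$X, 2, stats::sd) - sqrt(sd_orig))), 1e-9)

  z <- spectra_matrix(cbind(c(1, 2, 3), c(4, 4, 4)), c(2, 1))
  expect_warning(zu <- scale_variables(z, "uv"), "zero-variance")
  expect_equal(ncol(zu$matrix$X), 1)
  expect_equal(zu$dropped_ppm, 1)
})

test_that("recorded factors reproduce the processed matrix from raw data", {
  ds <- simulate_dataset(sim_config(n_per_class = 10, grid = c(9.5, 0.5, 300),
                                    seed = 3))
  pr <- preprocess(ds$matrix, excluded_regions = water_region(),
                   normalization = "pqn", scaling = "pareto")
  raw <- exclude_regions(ds$matrix, water_region())$X
  manual <- raw / pr$dilution_factors
  manual <- sweep(sweep(manual, 2, pr$centers), 2, pr$scales, "/")
  expect_lt(max(abs(manual - pr$matrix$X)), 1e-12)
})
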