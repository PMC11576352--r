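# Reference-pattern extraction, lag-scanned correlation matching, and the
# match/STOCSY refinement loop.

# cohort where acetate (isolated singlet at 1.92 ppm) occurs in exactly 17
# of 60 samples; jitter small enough to stay within the scanned lag range
presence_cohort <- function(seed = 33, noise_sd = 0, jitter = 0.002) {
  simulate_dataset(sim_config(
    n_classes = 2, n_per_class = 30,
    presence_count = list(acetate = 17),
    shift_jitter_sd = jitter, noise_sd = noise_sd,
    grid = c(9.5, 0.5, 4000), seed = seed))
}

acetate_pattern <- function(ds) {
  carriers <- ds$truth$sample_id[ds$truth$acetate > 0]
  src <- carriers[which.max(ds$truth$acetate[ds$truth$acetate > 0])]
  extract_reference(ds$matrix, src, 1.97, 1.87)
}

test_that("extract_reference centers the template and validates the window", {
  ds <- presence_cohort()
  pat <- acetate_pattern(ds)
  expect_lt(abs(mean(pat$template)), 1e-12)
  expect_gte(length(pat$template), 5)

  cm <- compass_match(ds$matrix, pat, max_shift_points = 3, threshold = 0.8)
  expect_equal(unname(cm$best_correlation[pat$source_sample]), 1,
               tolerance = 1e-12)
  expect_equal(unname(cm$best_shift[pat$source_sample]), 0)

  expect_error(extract_reference(ds$matrix, pat$source_sample, 1.921, 1.919),
               ">= 5")
  flat <- spectra_matrix(matrix(1, 2, 10), seq(5, 1, length.out = 10))
  expect_error(extract_reference(flat, "S1", 4.5, 1.5), "no pattern")
})

test_that("the pattern count recovers the simulated 17/60 presence exactly", {
  ds <- presence_cohort()
  pat <- acetate_pattern(ds)
  cm <- compass_match(ds$matrix, pat, max_shift_points = 6, threshold = 0.8)
  expect_equal(cm$n_containing, 17)
  expect_setequal(names(cm$contains_pattern)[cm$contains_pattern],
                  ds$truth$sample_id[ds$truth$acetate > 0])
})

test_that("best correlations match a brute-force sample x lag double loop", {
  ds <- presence_cohort(seed = 7)
  pat <- acetate_pattern(ds)
  cm <- compass_match(ds$matrix, pat, max_shift_points = 6, threshold = 0.8)
  win <- pat$window_indices
  for (i in seq_len(nrow(ds$matrix$X))) {
    best <- -Inf
    for (lg in -6:6) {
      seg <- ds$matrix$X[i, win + lg]
      r <- if (stats::sd(seg) > 0) stats::cor(pat$template, seg) else 0
      if (r > best) best <- r
    }
    expect_equal(unname(cm$best_correlation[i]), best, tolerance = 1e-12)
  }
})

test_that("matching is invariant to per-sample affine intensity transforms", {
  ds <- presence_cohort(seed = 12, noise_sd = 0.005)
  pat <- acetate_pattern(ds)
  cm1 <- compass_match(ds$matrix, pat, 2, 0.8)
  set.seed(4)
  a <- stats::runif(nrow(ds$matrix$X), 0.5, 3)
  b <- stats::rnorm(nrow(ds$matrix$X))
  m2 <- spectra_matrix(ds$matrix$X * a + b, ds$matrix$ppm,
                       sample_ids(ds$matrix))
  cm2 <- compass_match(m2, pat, 2, 0.8)
  expect_equal(cm1$best_correlation, cm2$best_correlation, tolerance = 1e-10)
})

test_that("threshold semantics: monotone count; threshold 1 needs exact shape", {
  ds <- presence_cohort(seed = 3, noise_sd = 0, jitter = 0)
  pat <- acetate_pattern(ds)
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95),
                   function(th) compass_match(ds$matrix, pat, 3, th)$n_containing,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # zero jitter, zero noise: carriers hold an (up to tail overlap from other
  # compounds) exact scalar multiple of the template
  cm <- compass_match(ds$matrix, pat, 0, 1 - 1e-6)
  expect_setequal(names(cm$contains_pattern)[cm$contains_pattern],
                  ds$truth$sample_id[ds$truth$acetate > 0])
  expect_error(compass_match(ds$matrix, pat, 10000, 0.8), "admissible")
})

test_that("match/STOCSY iteration refines the pattern to a fixed point", {
  ds <- presence_cohort(seed = 19, noise_sd = 0, jitter = 0)
  pat <- acetate_pattern(ds)
  it1 <- compass_stocsy_iterate(ds$matrix, pat, 3, 0.8)
  expect_equal(it1$compass$n_containing, 17)
  # homogeneous matched subset: refined template is shape-identical
  expect_gt(stats::cor(it1$pattern$template, pat$template), 0.999)
  # iterating on the refined pattern does not change the count (fixed point)
  it2 <- compass_stocsy_iterate(ds$matrix, it1$pattern, 3, 0.8)
  expect_equal(it2$compass$n_containing, it1$compass$n_containing)

  # a matrix without any carrier yields no matches at a strict threshold
  non_carriers <- ds$truth$sample_id[ds$truth$acetate == 0]
  expect_error(compass_stocsy_iterate(subset_samples(ds$matrix, non_carriers),
                                      pat, 3, 0.99), "threshold")
})

test_that("subset STOCSY surfaces the compound's other resonances", {
  # lactate-only cohort, pattern on the 1.33 doublet: STOCSY on the matched
  # subset shows r ~ 1 at the 4.11 quartet
  ds <- simulate_dataset(sim_config(compounds = builtin_library()["lactate"],
                                    n_per_class = 15, noise_sd = 0,
                                    shift_jitter_sd = 0,
                                    grid = c(9.5, 0.5, 2000), seed = 9))
  pat <- extract_reference(ds$matrix, "sample_001", 1.38, 1.29)
  it <- compass_stocsy_iterate(ds$matrix, pat, 3, 0.8)
  quartet <- which.min(abs(it$stocsy$ppm - 4.110))
  expect_gt(it$stocsy$correlation[quartet], 0.95)
})
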