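# The paired-tissue generator and its recorded ground truth.

test_that("generated betas are valid and the draw is deterministic", {
  cfg <- synthetic_config(n_samples = 12, n_probes = 100, seed = 31)
  a <- generate_pair(cfg)
  b <- generate_pair(cfg)
  expect_identical(unclass(a$x), unclass(b$x))
  expect_identical(unclass(a$y), unclass(b$y))
  expect_identical(a$truth, b$truth)
  expect_true(all(unclass(a$x) >= 0 & unclass(a$x) <= 1))
  expect_true(all(unclass(a$y) >= 0 & unclass(a$y) <= 1))
  expect_setequal(unique(a$truth$class),
                  c("constitutive-high", "constitutive-low", "conserved",
                    "offset"))
  expect_equal(sum(a$metadata$outcome), round(0.3 * 12))
  # the caller's RNG stream is untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_pair(cfg))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("the identity limit reproduces the surrogate exactly", {
  cfg <- synthetic_config(n_samples = 8, n_probes = 50, noise_sd = 0,
                          fraction_offset_probes = 0, slope_sd = 0,
                          fraction_uncoupled = 0,
                          fraction_outcome_probes = 0,
                          fraction_constitutive_high = 0,
                          fraction_constitutive_low = 0, seed = 2)
  pair <- generate_pair(cfg)
  expect_identical(unclass(pair$y), unclass(pair$x))
})

test_that("the offset fraction controls the share of shifted CpGs", {
  cfg <- synthetic_config(n_samples = 30, n_probes = 1500,
                          fraction_offset_probes = 0.14, seed = 13)
  pair <- generate_pair(cfg)
  diffs <- colMeans(abs(unclass(pair$x) - unclass(pair$y)))
  frac_shifted <- mean(diffs > 0.1)
  expect_equal(frac_shifted, 0.14, tolerance = 0.35)
  # offset probes recorded in truth carry |offset| >= 0.1
  off <- pair$truth[pair$truth$class == "offset", ]
  expect_true(all(abs(off$offset) >= 0.1))
  expect_equal(nrow(off), round(0.14 * 1500))
})

test_that("cross-tissue correlation degrades with noise", {
  mean_r2 <- vapply(c(0.005, 0.05, 0.15), function(ns) {
    vals <- vapply(c(41, 42), function(seed) {
      cfg <- synthetic_config(n_samples = 14, n_probes = 300, noise_sd = ns,
                              seed = seed)
      pair <- generate_pair(cfg)
      cross_tissue_correlation(pair$x, pair$y, filters = list(NULL))$mean_r2
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("intensity inversion reproduces betas and honors failure rates", {
  # hand example: beta 0.5 with total signal 2000 gives M = 1000, U = 900
  b1 <- beta_matrix(matrix(0.5, 1, 1, dimnames = list("s1", "cg1")))
  iset1 <- generate_intensity_set(b1, total_signal = 2000, offset = 100)
  expect_equal(as.numeric(iset1$methylated), 1000)
  expect_equal(as.numeric(iset1$unmethylated), 900)

  withr::with_seed(6, {
    b <- bm(matrix(runif(60, 0.001, 0.999), 6, 10))
  })
  iset <- generate_intensity_set(b, total_signal = 8000)
  back <- compute_beta(iset, offset = 100)
  expect_equal(unclass(back), unclass(b), tolerance = 1e-9)
  expect_true(all(iset$detection_p == 0))
  expect_true(all(iset$bead_count == 30L))

  isetf <- generate_intensity_set(b, detection_fail_rate = 0.3,
                                  bead_fail_rate = 0.2, seed = 8)
  expect_gt(sum(isetf$detection_p > 0), 0)
  expect_gt(sum(isetf$bead_count < 3), 0)
  expect_error(generate_intensity_set(b, total_signal = -5), "positive")
})

test_that("truth recovery: fitted models match the generating affine map", {
  cfg <- synthetic_config(n_samples = 40, n_probes = 300, noise_sd = 0.01,
                          fraction_constitutive_high = 0,
                          fraction_constitutive_low = 0,
                          sample_sd_range = c(0.05, 0.2), seed = 47)
  pair <- generate_pair(cfg)
  fit <- fit_probe_models(pair$x, pair$y, method = "LM", quiet = TRUE)
  ok <- pair$truth$frac_truncated == 0
  expect_gt(cor(fit$coefficients$slope[ok], pair$truth$slope[ok]), 0.99)
  expect_gt(cor(fit$coefficients$intercept[ok], pair$truth$intercept[ok]), 0.98)
})

test_that("written synthetic studies round-trip through the TSV dialect", {
  dir <- withr::local_tempdir()
  pair <- generate_pair(synthetic_config(n_samples = 6, n_probes = 20, seed = 3))
  paths <- write_synthetic_pair(pair, dir)
  expect_true(all(file.exists(paths)))
  back <- read_beta_matrix(paths[["x"]])
  expect_equal(unclass(back), unclass(pair$x))
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$seed, 3)
  expect_equal(manifest$n_probes, 20)
})
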