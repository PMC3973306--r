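# Per-probe calibration engines.

test_that("fit_linear_probe recovers exact lines and matches the OLS oracle", {
  m <- fit_linear_probe(c(0.1, 0.2, 0.3), c(0.25, 0.45, 0.65))
  expect_equal(m$intercept, 0.05)
  expect_equal(m$slope, 2.0)

  ident <- fit_linear_probe(c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8))
  expect_equal(ident$intercept, 0)
  expect_equal(ident$slope, 1)

  m2 <- fit_linear_probe(c(0, 1, 0, 1), c(0.2, 0.8, 0.3, 0.7))
  expect_equal(c(m2$intercept, m2$slope), oracle_ols(c(0, 1, 0, 1),
                                                     c(0.2, 0.8, 0.3, 0.7)))
  expect_equal(m2$slope, 0.5)
  expect_equal(m2$intercept, 0.25)
})

test_that("fit_linear_probe flags constant predictors and short inputs", {
  cm <- fit_linear_probe(rep(0.4, 5), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_identical(cm$flag, "constant_x")
  expect_equal(predict_linear_probe(cm, c(0, 5)), rep(0.3, 2),
               ignore_attr = TRUE)

  short <- fit_linear_probe(c(0.1, NA), c(0.2, 0.3))
  expect_identical(short$flag, "insufficient_data")
  expect_true(all(is.na(predict_linear_probe(short, c(0.1, 0.2)))))
})

test_that("predict_linear_probe preserves out-of-range values and counts them", {
  m <- structure(list(probe_id = "p", intercept = 0.9, slope = 1.5,
                      n_obs = 10, flag = "ok"), class = "linear_probe_model")
  p <- predict_linear_probe(m, 0.5)
  expect_equal(as.numeric(p), 1.65)
  expect_equal(attr(p, "n_out_of_range"), 1)
  pc <- predict_linear_probe(m, 0.5, clamp = TRUE)
  expect_equal(as.numeric(pc), 1)

  ident <- fit_linear_probe(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(as.numeric(predict_linear_probe(ident, 0.37)), 0.37)
})

test_that("linear fitting equals the normal-equations oracle on random instances", {
  withr::with_seed(101, {
    for (i in seq_len(200)) {
      n <- sample(3:20, 1)
      x <- runif(n)
      y <- runif(n)
      if (sd(x) == 0) next
      m <- fit_linear_probe(x, y)
      o <- oracle_ols(x, y)
      expect_true(abs(m$intercept - o[1]) < 1e-10)
      expect_true(abs(m$slope - o[2]) < 1e-10)
    }
  })
})

test_that("SVR handles constant targets and tracks a noisy line", {
  const <- fit_svr_probe(runif(10), rep(0.5, 10))
  expect_identical(const$flag, "constant_y")
  expect_equal(predict_svr_probe(const, c(0.1, 0.9, -3)), rep(0.5, 3))

  withr::with_seed(33, {
    x <- runif(30, 0.1, 0.9)
    y <- 0.1 + 0.8 * x + rnorm(30, 0, 0.01)
    m <- fit_svr_probe(x, y)
    expect_lt(abs(predict_svr_probe(m, 0.5) - 0.5), 0.05)
  })
})

test_that("SVR predictions never leave the training-target range", {
  withr::with_seed(7, {
    for (i in seq_len(20)) {
      x <- runif(15)
      y <- pmin(pmax(0.3 + 0.5 * x + rnorm(15, 0, 0.1), 0), 1)
      m <- fit_svr_probe(x, y)
      queries <- c(runif(5), -10, 10, 1e3, -1e3)
      p <- predict_svr_probe(m, queries)
      expect_true(all(p >= m$training_y_range[1] - 1e-12))
      expect_true(all(p <= m$training_y_range[2] + 1e-12))
    }
  })
})

test_that("fit_probe_models fits per probe on pairwise-complete data", {
  pair <- affine_pair(n = 10, m = 5)
  ident <- fit_probe_models(pair$x, pair$x, method = "LM", quiet = TRUE)
  expect_equal(ident$coefficients$slope, rep(1, 5))
  expect_equal(ident$coefficients$intercept, rep(0, 5))

  xm <- unclass(pair$x); xm[1, 1] <- NA
  fit <- fit_probe_models(beta_matrix(xm), pair$y, method = "LM", quiet = TRUE)
  expect_equal(fit$coefficients$n_obs[1], 9L)
  expect_equal(fit$coefficients$n_obs[2], 10L)

  svr <- fit_probe_models(beta_matrix(xm), pair$y, method = "SVR", quiet = TRUE)
  expect_identical(names(svr$models), fit$coefficients$probe_id)
})

test_that("predict_matrix applies models elementwise with missing propagation", {
  pair <- affine_pair(n = 8, m = 4)
  ident <- fit_probe_models(pair$x, pair$x, method = "LM", quiet = TRUE)
  xm <- unclass(pair$x); xm[2, 3] <- NA
  p <- predict_matrix(ident, beta_matrix(xm))
  expect_true(is.na(p[2, 3]))
  expect_equal(p[-2, ], unclass(pair$x)[-2, ], tolerance = 1e-12)

  other <- bm(matrix(runif(4), 2, 2), probes = c("zz1", "zz2"))
  expect_error(predict_matrix(ident, other), "zz1")

  svr <- fit_probe_models(pair$x, pair$y, method = "SVR", quiet = TRUE)
  ps <- predict_matrix(svr, beta_matrix(xm))
  rng <- vapply(svr$models, `[[`, numeric(2), "training_y_range")
  for (j in seq_len(ncol(ps))) {
    ok <- !is.na(ps[, j])
    expect_true(all(ps[ok, j] >= rng[1, j] & ps[ok, j] <= rng[2, j]))
  }
})

test_that("prediction is equivariant under sample reordering", {
  pair <- affine_pair(n = 9, m = 4, noise_sd = 0.01)
  fit <- fit_probe_models(pair$x, pair$y, method = "LM", quiet = TRUE)
  p1 <- predict_matrix(fit, pair$x)
  perm <- c(3, 1, 2, 9, 5, 4, 6, 8, 7)
  p2 <- predict_matrix(fit, beta_matrix(unclass(pair$x)[perm, ]))
  expect_equal(p2, p1[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fitted slopes recover generating slopes on affine synthetic data", {
  cfg <- synthetic_config(n_samples = 30, n_probes = 400, noise_sd = 0.02,
                          fraction_constitutive_high = 0,
                          fraction_constitutive_low = 0,
                          sample_sd_range = c(0.05, 0.2), seed = 19)
  pair <- generate_pair(cfg)
  fit <- fit_probe_models(pair$x, pair$y, method = "LM", quiet = TRUE)
  ok <- pair$truth$frac_truncated == 0
  expect_gt(cor(fit$coefficients$slope[ok], pair$truth$slope[ok]), 0.99)
})
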