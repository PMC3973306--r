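# Multi-probe extension: predictor selection and multivariate fits.

test_that("predictor selection forces the same-id probe and ranks by |r|", {
  withr::with_seed(8, {
    n <- 20
    x <- matrix(runif(n * 5), n, 5)
    y <- x[, 3] + rnorm(n, 0, 0.05)          # cg3 is the duplicated signal
    x[, 5] <- y                               # cg5 equals the target exactly
    X <- bm(pmin(pmax(x, 0), 1))
    y <- unclass(X)[, 5]
    sel1 <- select_multiprobe_predictors(X, y, "cg1", K = 1)
    expect_identical(sel1, "cg1")
    sel2 <- select_multiprobe_predictors(X, y, "cg1", K = 2)
    expect_identical(sel2, c("cg1", "cg5"))  # |r| = 1 is maximal
    expect_error(select_multiprobe_predictors(X, y, "cg1", K = n - 1),
                 "overparameterized")
  })
})

test_that("ties in |r| break lexicographically by probe id", {
  # two candidate probes exactly duplicating each other
  n <- 10
  base <- seq(0.1, 0.9, length.out = n)
  x <- cbind(a = runif(n, 0.2, 0.8), zz = base, bb = base)
  X <- beta_matrix(x, sample_ids = paste0("s", 1:n), probe_ids = colnames(x))
  y <- base
  sel <- select_multiprobe_predictors(X, y, "a", K = 2)
  expect_identical(sel, c("a", "bb"))
})

test_that("K = 1 multi-probe coefficients equal the single-probe linear model exactly", {
  pair <- affine_pair(n = 15, m = 6, noise_sd = 0.02, seed = 3)
  mp <- fit_multiprobe(pair$x, pair$y, target_probes = colnames(pair$y), K = 1)
  lm1 <- fit_probe_models(pair$x, pair$y, method = "LM", quiet = TRUE)
  for (pid in colnames(pair$y)) {
    cf <- mp$models[[pid]]$coefficients
    single <- fit_linear_probe(unclass(pair$x)[, pid], unclass(pair$y)[, pid])
    expect_identical(unname(cf[1]), single$intercept)
    expect_identical(unname(cf[2]), single$slope)
    # and the vectorized matrix fitter agrees to numerical precision
    row <- lm1$coefficients[lm1$coefficients$probe_id == pid, ]
    expect_equal(unname(cf[1]), row$intercept, tolerance = 1e-10)
    expect_equal(unname(cf[2]), row$slope, tolerance = 1e-10)
  }
})

test_that("an exactly representable target has zero residuals", {
  withr::with_seed(12, {
    n <- 20
    x <- matrix(runif(n * 3, 0.2, 0.8), n, 3)
    x[, 1] <- 0.5 * x[, 2] + 0.5 * x[, 3]   # target probe = linear combo
    X <- bm(x)
    Y <- X
    # cg1 = 0.5 cg2 + 0.5 cg3 also makes the design collinear by design
    mp <- suppressWarnings(fit_multiprobe(X, Y, target_probes = "cg1", K = 3))
    pred <- predict_multiprobe(mp, X)
    expect_equal(pred[, "cg1"], unclass(Y)[, "cg1"], tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
})

test_that("collinear predictors are dropped with a warning and the fit proceeds", {
  n <- 12
  withr::with_seed(21, {
    base <- runif(n, 0.2, 0.8)
    x <- cbind(t1 = base, dup1 = base, other = runif(n, 0.2, 0.8))
    X <- beta_matrix(x, sample_ids = paste0("s", 1:n), probe_ids = colnames(x))
    y <- unclass(X)
    expect_warning(mp <- fit_multiprobe(X, X, target_probes = "t1", K = 3),
                   "collinear")
    expect_identical(mp$models[["t1"]]$flag, "ok")
  })
})

test_that("a second informative predictor raises cross-validated accuracy", {
  withr::with_seed(55, {
    n <- 30
    x_same <- runif(n, 0.2, 0.8)
    x_other <- runif(n, 0.2, 0.8)
    noise <- matrix(runif(n * 8, 0.2, 0.8), n, 8)
    X <- beta_matrix(cbind(tgt = x_same, aux = x_other, noise),
                     sample_ids = paste0("s", 1:n),
                     probe_ids = c("tgt", "aux", paste0("n", 1:8)))
    y <- 0.5 * x_same + 0.5 * x_other + rnorm(n, 0, 0.01)
    Y <- X; Y[, "tgt"] <- pmin(pmax(y, 0), 1)
    Y <- beta_matrix(unclass(Y))
    sc <- cv_scheme("leave-one-sample-out")
    r2 <- vapply(c(1, 2), function(K) {
      cv <- cross_validate(X, Y, sc, method = "multiprobe-LM", K = K,
                           target_probes = "tgt")
      cv$report$per_probe$r2[1]
    }, numeric(1))
    expect_gt(r2[2], r2[1])
  })
})

test_that("evaluation-probe selection respects bounds, seed, and exhaustion", {
  withr::with_seed(2, {
    m <- 30
    sds <- runif(m, 0, 0.3)
    vals <- matrix(rep(0.5, 10 * m), 10, m) + outer(rnorm(10), sds)
    y <- bm(pmin(pmax(vals, 0), 1))
    real_sds <- apply(unclass(y), 2, sd)
    r2 <- setNames(runif(m, 0, 1), colnames(y))
    sel <- suppressWarnings(
      select_target_probes_for_multiprobe(y, r2, sd_range = c(0.1, 0.2),
                                          r2_max = 0.3, count = 1000, seed = 1))
    expect_true(all(real_sds[sel] >= 0.1 & real_sds[sel] <= 0.2))
    expect_true(all(r2[sel] < 0.3))
    expect_warning(
      select_target_probes_for_multiprobe(y, r2, count = 1000, seed = 1),
      "eligible")
    a <- select_target_probes_for_multiprobe(y, r2, sd_range = c(0, 1),
                                             r2_max = 2, count = 5, seed = 9)
    b <- select_target_probes_for_multiprobe(y, r2, sd_range = c(0, 1),
                                             r2_max = 2, count = 5, seed = 9)
    expect_identical(a, b)
  })
})
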