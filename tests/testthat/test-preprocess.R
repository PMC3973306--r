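# Normalization and filtering chain.

test_that("compute_beta follows M / (M + U + offset) and stays below 1", {
  iset <- intensity_set(
    methylated = matrix(c(0, 1000, 900), 1, 3,
                        dimnames = list("s1", c("p1", "p2", "p3"))),
    unmethylated = matrix(c(0, 900, 0), 1, 3,
                          dimnames = list("s1", c("p1", "p2", "p3"))))
  b <- compute_beta(iset, offset = 100)
  expect_equal(as.numeric(unclass(b)), c(0, 0.5, 0.9))

  # strictly below 1 whenever offset > 0
  big <- intensity_set(matrix(1e7, 2, 2), matrix(0, 2, 2))
  expect_true(all(unclass(compute_beta(big, offset = 100)) < 1))

  expect_error(intensity_set(matrix(-1, 1, 1), matrix(0, 1, 1)), "nonnegative")
})

test_that("mask_low_quality masks on strict detection-p and bead thresholds", {
  vals <- matrix(0.5, 1, 3, dimnames = list("s1", c("p1", "p2", "p3")))
  beta <- beta_matrix(vals)
  iset <- intensity_set(vals * 1000, vals * 1000,
                        detection_p = matrix(c(0.04, 0.051, 0.01), 1, 3),
                        bead_count = matrix(c(10, 10, 2), 1, 3))
  thr <- quality_thresholds(detection_p_max = 0.05, min_bead_count = 3)
  masked <- mask_low_quality(beta, iset, thr)
  expect_equal(as.numeric(is.na(masked)), c(0, 1, 1))

  # exactly at the threshold is retained ("P > 0.05" masks)
  iset2 <- intensity_set(vals * 1000, vals * 1000,
                         detection_p = matrix(c(0.05, 0.05, 0.05), 1, 3))
  thr2 <- quality_thresholds(detection_p_max = 0.05, min_bead_count = 0)
  expect_false(anyNA(mask_low_quality(beta, iset2, thr2)))

  wrong <- intensity_set(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_error(mask_low_quality(beta, wrong, thr), "share dimensions")
})

test_that("drop_failed_samples uses a strict missingness threshold", {
  vals <- matrix(0.5, 3, 100)
  vals[1, 1:21] <- NA       # 21% missing -> dropped
  vals[2, 1:20] <- NA       # exactly 20% -> retained
  b <- bm(vals)
  out <- drop_failed_samples(b, quality_thresholds(), quiet = TRUE)
  expect_identical(rownames(out), c("s2", "s3"))
  expect_identical(attr(out, "dropped_samples"), "s1")

  clean <- bm(matrix(0.5, 2, 4))
  expect_identical(unclass(drop_failed_samples(clean, quiet = TRUE))[, ],
                   unclass(clean)[, ])
  allbad <- bm(matrix(NA_real_, 2, 4))
  expect_error(drop_failed_samples(allbad), "All samples")
})

test_that("quantile_normalize matches the rank-mean oracle", {
  m <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[1, ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[2, ]), c(2.5, 3.5, 4.5))

  # identical samples are a fixed point
  same <- rbind(a = c(0.2, 0.7, 0.4), b = c(0.2, 0.7, 0.4))
  expect_equal(quantile_normalize(same), same)

  # permuted samples end up with the same multiset of values
  p <- rbind(a = c(5, 1, 3), b = c(1, 3, 5))
  out2 <- quantile_normalize(p)
  expect_equal(sort(out2[1, ]), sort(out2[2, ]))

  # complete-data invariants: identical sorted vectors, total sum preserved
  withr::with_seed(4, {
    big <- matrix(rnorm(5 * 50), 5, 50)
    nb <- quantile_normalize(big)
    sorted <- apply(nb, 1, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    expect_equal(sum(nb), sum(big))
  })

  expect_error(quantile_normalize(rbind(c(1, NA, NA), c(1, 2, 3))),
               "non-missing")
})

test_that("type II alignment maps onto the type I distribution per category", {
  withr::with_seed(9, {
    n_I <- 51; n_II <- 31
    probes <- c(paste0("I", seq_len(n_I)), paste0("II", seq_len(n_II)))
    ann <- toy_annotation(probes, c(rep("I", n_I), rep("II", n_II)))
    xI <- sort(runif(n_I, 0.1, 0.9))
    xII <- sort(runif(n_II, 0.3, 0.99))
    b <- beta_matrix(matrix(c(xI, xII), 1, dimnames = list("s1", probes)))
    out <- align_typeII_to_typeI(b, ann)
    # type I untouched
    expect_equal(unclass(out)[1, seq_len(n_I)], xI, ignore_attr = TRUE)
    # the type II median maps to the type I median
    med_idx <- n_I + (n_II + 1) / 2
    expect_equal(unname(unclass(out)[1, med_idx]), median(xI), tolerance = 1e-12)
    # monotone within category/sample
    mapped <- unclass(out)[1, n_I + seq_len(n_II)]
    expect_true(all(diff(mapped) >= 0))
  })
})

test_that("type II alignment is a near-identity for matching distributions", {
  vals <- seq(0.05, 0.95, length.out = 20)
  probes <- paste0("cg", seq_len(40))
  ann <- toy_annotation(probes, rep(c("I", "II"), each = 20))
  b <- beta_matrix(matrix(c(vals, vals), 1, dimnames = list("s1", probes)))
  out <- align_typeII_to_typeI(b, ann)
  spacing <- max(diff(vals))
  expect_true(all(abs(unclass(out)[1, 21:40] - vals) <= spacing))
})

test_that("type II alignment errors on a category without type I probes", {
  ann <- toy_annotation(c("a", "b"), c("II", "II"), category = "shelf")
  b <- beta_matrix(matrix(c(0.4, 0.6), 1, dimnames = list("s1", c("a", "b"))))
  expect_error(align_typeII_to_typeI(b, ann), "shelf")
})

test_that("filter_snp_probes drops flagged probes only", {
  b <- bm(matrix(runif(6), 2, 3))
  ann <- toy_annotation(colnames(b), c("I", "I", "II"),
                        snp_flag = c(FALSE, TRUE, FALSE))
  out <- filter_snp_probes(b, ann, quiet = TRUE)
  expect_identical(colnames(out), c("cg1", "cg3"))

  ann0 <- toy_annotation(colnames(b), c("I", "I", "II"), snp_flag = FALSE)
  expect_identical(colnames(filter_snp_probes(b, ann0, quiet = TRUE)),
                   colnames(b))
  annall <- toy_annotation(colnames(b), c("I", "I", "II"), snp_flag = TRUE)
  expect_warning(out0 <- filter_snp_probes(b, annall, quiet = TRUE),
                 "All probes")
  expect_equal(ncol(out0), 0)
})

test_that("extreme-probe filter removes constitutive probes and nests", {
  # probe 1 constitutively high, probe 2 mid-range, probe 3 constitutively low
  x <- bm(rbind(c(0.92, 0.30, 0.05), c(0.95, 0.70, 0.08)))
  y <- bm(rbind(c(0.99, 0.40, 0.06), c(0.93, 0.60, 0.07)))
  kept <- filter_extreme_probes(list(x, y), extreme_probe_filter(0.9, 0.1))
  expect_identical(as.character(kept), "cg2")
  expect_setequal(attr(kept, "removed"), c("cg1", "cg3"))

  # vacuous filter retains everything
  kept_all <- filter_extreme_probes(list(x, y), extreme_probe_filter(1, 0))
  expect_setequal(as.character(kept_all), colnames(x))

  # mid-range probe survives both standard levels
  expect_true("cg2" %in% filter_extreme_probes(list(x, y),
                                               extreme_probe_filter(0.8, 0.2)))

  # nestedness on a random pool
  withr::with_seed(2, {
    pool <- bm(matrix(runif(400), 8, 50))
    loose <- filter_extreme_probes(pool, extreme_probe_filter(0.9, 0.1))
    strict <- filter_extreme_probes(pool, extreme_probe_filter(0.8, 0.2))
    expect_true(all(strict %in% loose))
  })

  expect_error(filter_extreme_probes(bm(matrix(NA_real_, 2, 2))), "Empty pool")
})

test_that("profile chains run end to end", {
  withr::with_seed(5, {
    b <- bm(matrix(runif(80, 0.1, 0.9), 4, 20))
    iset <- generate_intensity_set(b, total_signal = 5000)
    out27 <- normalize_27k(iset)
    expect_s3_class(out27, "beta_matrix")
    expect_equal(dim(out27), dim(b))

    ann <- toy_annotation(colnames(b), rep(c("I", "II"), 10),
                          category = rep(c("island", "shore"), each = 10))
    out450 <- normalize_450k(b, intensities = iset, ann = ann)
    expect_s3_class(out450, "beta_matrix")
    expect_true(length(attr(out450, "log")) >= 4)
  })
})
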