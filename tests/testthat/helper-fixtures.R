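# Shared fixtures and independent oracles for the test suite.

# quick beta_matrix from a plain matrix with auto ids
bm <- function(values, samples = NULL, probes = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (is.null(probes)) probes <- paste0("cg", seq_len(ncol(values)))
  beta_matrix(values, sample_ids = samples, probe_ids = probes)
}

# independent OLS oracle: brute-force normal equations on the design matrix
oracle_ols <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  A <- cbind(1, x[ok])
  as.vector(solve(crossprod(A), crossprod(A, y[ok])))
}

# a small aligned pair with an exact per-probe affine relation
affine_pair <- function(n = 12, m = 6, intercepts = NULL, slopes = NULL,
                        noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(intercepts)) intercepts <- runif(m, -0.05, 0.05)
    if (is.null(slopes)) slopes <- runif(m, 0.6, 1.2)
    x <- matrix(runif(n * m, 0.2, 0.8), n, m)
    y <- sweep(sweep(x, 2, slopes, `*`), 2, intercepts, `+`) +
      matrix(rnorm(n * m, 0, noise_sd), n, m)
    y <- pmin(pmax(y, 0), 1)
    list(x = bm(x), y = bm(y), intercepts = intercepts, slopes = slopes)
  })
}

# four-probe annotation covering both design types in one category
toy_annotation <- function(probes, design_type, category = "island",
                           snp_flag = FALSE) {
  tibble::tibble(probe_id = probes,
                 design_type = design_type,
                 category = rep_len(category, length(probes)),
                 snp_flag = rep_len(snp_flag, length(probes)))
}
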