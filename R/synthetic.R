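# Synthetic paired-tissue generator. Emulates the statistical structure the
# calibration method relies on: U-shaped (bimodal) beta distributions with
# constitutively methylated/unmethylated probes, high between-tissue
# correlation, a minority of probes with consistent cross-tissue mean
# shifts, per-probe affine tissue relationships plus technical noise,
# family clustering of samples, and a binary outcome that can act on the
# target tissue only. Ground truth (per-probe class, intercept, slope,
# outcome effect) is recorded for recovery tests.

#' Configuration for the synthetic paired-tissue generator
#'
#' Defaults describe a study of 40 related individuals (20 families of two,
#' matching the scale of a family-based methylation study) and 2000 probes.
#' Probe classes partition the array: constitutively methylated (means near
#' 0.95) and unmethylated (near 0.05) probes jointly about 40% -- the
#' share the (0.9, 0.1) extreme filter typically removes -- plus offset
#' probes carrying a consistent cross-tissue mean shift of at least 0.1
#' (the "differing CpG" fraction real tissue pairs put at 14-26%), the rest
#' conserved. The target tissue is a per-probe affine transform of the
#' surrogate pivoting at the probe mean (`y = mu_y + b (x - mu_x) + e`)
#' with slopes spread around 1, plus Gaussian technical noise; all betas
#' are truncated to the open interval \[0.001, 0.999\], which mirrors the
#' fact that the beta formula with a positive offset never reaches the
#' bounds and makes intensity inversion well defined.
#'
#' @param n_samples Number of individuals (split into families).
#' @param n_probes Number of CpG probes.
#' @param family_sizes Integer vector summing to `n_samples`; default
#'   families of 2 (plus one odd singleton if needed).
#' @param fraction_constitutive_high,fraction_constitutive_low Fractions of
#'   probes pinned near 1 / near 0 in both tissues.
#' @param fraction_offset_probes Fraction with a consistent cross-tissue
#'   mean shift > `offset_min`.
#' @param offset_min Minimum |mean shift| of offset probes, default 0.1.
#' @param offset_sd_between_probes Spread of offset magnitudes across
#'   probes, default 0.08.
#' @param slope_mean,slope_sd Per-probe slope distribution for conserved and
#'   offset probes, default N(1, 0.35): cross-tissue scale relationships
#'   vary widely around proportionality.
#' @param fraction_uncoupled Fraction of non-constitutive probes whose
#'   target methylation is tissue-autonomous: the slope is drawn near 0
#'   (N(0, 0.05)), so surrogate variation at these CpGs carries no target
#'   information -- the regime where a raw surrogate misleads and
#'   calibration shrinks the probe instead. Default 0.1.
#' @param sample_sd_range Per-probe between-individual SD of the surrogate,
#'   drawn uniformly from this range for non-constitutive probes, default
#'   (0.03, 0.15); constitutive probes use (0.005, 0.02).
#' @param family_icc Share of between-individual variance explained by a
#'   shared per-family random intercept, default 0.3.
#' @param noise_sd Technical noise SD added to the target tissue, default
#'   0.02 (the scale of array replicate noise).
#' @param fraction_outcome_probes Fraction of non-constitutive probes whose
#'   target-tissue methylation responds to the outcome, default 0.05.
#' @param outcome_effect_sd SD of the per-probe outcome effect (added to
#'   target-tissue cases), default 0.08.
#' @param case_fraction Fraction of case samples, default 0.3.
#' @param mean_range Range of surrogate probe means for non-constitutive
#'   probes, default (0.1, 0.9).
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 40, n_probes = 2000,
                             family_sizes = NULL,
                             fraction_constitutive_high = 0.2,
                             fraction_constitutive_low = 0.2,
                             fraction_offset_probes = 0.15,
                             offset_min = 0.1,
                             offset_sd_between_probes = 0.08,
                             slope_mean = 1, slope_sd = 0.35,
                             fraction_uncoupled = 0.1,
                             sample_sd_range = c(0.03, 0.15),
                             family_icc = 0.3,
                             noise_sd = 0.02,
                             fraction_outcome_probes = 0.05,
                             outcome_effect_sd = 0.08,
                             case_fraction = 0.3,
                             mean_range = c(0.1, 0.9),
                             seed = 1) {
  if (is.null(family_sizes)) {
    family_sizes <- rep(2L, n_samples %/% 2)
    if (n_samples %% 2 == 1) family_sizes <- c(family_sizes, 1L)
  }
  if (sum(family_sizes) != n_samples) {
    abort("`family_sizes` must sum to `n_samples`.")
  }
  fracs <- c(fraction_constitutive_high, fraction_constitutive_low,
             fraction_offset_probes, fraction_outcome_probes, case_fraction,
             fraction_uncoupled)
  if (any(fracs < 0 | fracs > 1)) abort("Fractions must lie in [0, 1].")
  if (fraction_constitutive_high + fraction_constitutive_low >= 1) {
    abort("Constitutive fractions must sum to < 1.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!(family_icc >= 0 && family_icc < 1)) abort("`family_icc` must be in [0, 1).")
  structure(
    list(n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
         family_sizes = as.integer(family_sizes),
         fraction_constitutive_high = fraction_constitutive_high,
         fraction_constitutive_low = fraction_constitutive_low,
         fraction_offset_probes = fraction_offset_probes,
         offset_min = offset_min,
         offset_sd_between_probes = offset_sd_between_probes,
         slope_mean = slope_mean, slope_sd = slope_sd,
         fraction_uncoupled = fraction_uncoupled,
         sample_sd_range = sample_sd_range, family_icc = family_icc,
         noise_sd = noise_sd,
         fraction_outcome_probes = fraction_outcome_probes,
         outcome_effect_sd = outcome_effect_sd,
         case_fraction = case_fraction, mean_range = mean_range,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

.trunc_beta <- function(v, lo = 0.001, hi = 0.999) pmin(pmax(v, lo), hi)

#' Generate a paired surrogate/target beta-matrix study
#'
#' Draws a full synthetic study from a [synthetic_config()]: surrogate
#' matrix X, target matrix Y, sample metadata (family and case/control
#' outcome) and the generating truth. Deterministic given the config seed;
#' the caller's RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_pair` with elements `x`, `y`
#'   (`beta_matrix`), `metadata` (tibble: sample_id, family_id, outcome),
#'   `truth` (tibble: per-probe class, mu_x, mu_y, intercept, slope,
#'   sample_sd, offset, outcome_effect, frac_truncated), and `config`.
#' @export
generate_pair <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_pair_impl(config))
}

.generate_pair_impl <- function(cfg) {
  n <- cfg$n_samples; m <- cfg$n_probes
  sample_ids <- sprintf("s%03d", seq_len(n))
  family_ids <- rep(sprintf("f%03d", seq_along(cfg$family_sizes)),
                    times = cfg$family_sizes)
  n_cases <- round(cfg$case_fraction * n)
  outcome <- rep(0L, n)
  outcome[sample(n, n_cases)] <- 1L

  # probe classes partition the array
  n_ch <- round(cfg$fraction_constitutive_high * m)
  n_cl <- round(cfg$fraction_constitutive_low * m)
  n_off <- round(cfg$fraction_offset_probes * m)
  if (n_ch + n_cl + n_off > m) abort("Probe-class fractions exceed 1.")
  cls <- rep("conserved", m)
  idx <- sample(m)
  cls[idx[seq_len(n_ch)]] <- "constitutive-high"
  if (n_cl > 0) cls[idx[n_ch + seq_len(n_cl)]] <- "constitutive-low"
  if (n_off > 0) cls[idx[n_ch + n_cl + seq_len(n_off)]] <- "offset"
  probe_ids <- sprintf("cg%07d", seq_len(m))

  mu_x <- numeric(m); tau <- numeric(m)
  ch <- cls == "constitutive-high"; cl <- cls == "constitutive-low"
  mid <- !(ch | cl)
  mu_x[ch] <- rbeta(sum(ch), 40, 2.5)       # peak near 0.94
  mu_x[cl] <- rbeta(sum(cl), 2.5, 40)       # peak near 0.06
  mu_x[mid] <- runif(sum(mid), cfg$mean_range[1], cfg$mean_range[2])
  tau[ch | cl] <- runif(sum(ch | cl), 0.005, 0.02)
  tau[mid] <- runif(sum(mid), cfg$sample_sd_range[1], cfg$sample_sd_range[2])

  # cross-tissue map: slope pivots at the probe mean; offset probes add a
  # consistent mean shift
  slope <- rep(1, m)
  slope[mid] <- rnorm(sum(mid), cfg$slope_mean, cfg$slope_sd)
  uncoupled <- rep(FALSE, m)
  if (cfg$fraction_uncoupled > 0 && any(mid)) {
    n_unc <- round(cfg$fraction_uncoupled * sum(mid))
    unc_idx <- sample(which(mid), n_unc)
    uncoupled[unc_idx] <- TRUE
    slope[unc_idx] <- rnorm(n_unc, 0, 0.05)
  }
  off <- rep(0, m)
  is_off <- cls == "offset"
  if (any(is_off)) {
    magnitude <- cfg$offset_min + abs(rnorm(sum(is_off), 0,
                                            cfg$offset_sd_between_probes))
    off[is_off] <- magnitude * sample(c(-1, 1), sum(is_off), replace = TRUE)
  }
  mu_y <- .trunc_beta(mu_x + off, 0.02, 0.98)
  intercept <- mu_y - slope * mu_x

  # outcome effects on the target tissue only
  outcome_effect <- rep(0, m)
  eligible <- which(mid)
  n_out <- round(cfg$fraction_outcome_probes * m)
  if (n_out > 0 && length(eligible) > 0) {
    hit <- sample(eligible, min(n_out, length(eligible)))
    outcome_effect[hit] <- rnorm(length(hit), 0, cfg$outcome_effect_sd)
  }

  # surrogate: probe mean + shared family intercept + individual deviation
  fam_sd <- tau * sqrt(cfg$family_icc)
  ind_sd <- tau * sqrt(1 - cfg$family_icc)
  n_fam <- length(cfg$family_sizes)
  fam_of <- rep(seq_len(n_fam), times = cfg$family_sizes)
  u <- matrix(rnorm(n_fam * m), n_fam, m) * rep(fam_sd, each = n_fam)
  e <- matrix(rnorm(n * m), n, m) * rep(ind_sd, each = n)
  x_raw <- rep(mu_x, each = n) + u[fam_of, ] + e
  x <- .trunc_beta(x_raw)

  # target: affine transform of the observed surrogate + outcome + noise
  y_lin <- sweep(sweep(x, 2, slope, `*`), 2, intercept, `+`) +
    outer(as.numeric(outcome), outcome_effect)
  y_raw <- y_lin + matrix(rnorm(n * m, 0, cfg$noise_sd), n, m)
  y <- .trunc_beta(y_raw)

  frac_trunc <- colMeans((x_raw != x) | (y_raw != y))
  dimnames(x) <- list(sample_ids, probe_ids)
  dimnames(y) <- list(sample_ids, probe_ids)
  list(
    x = beta_matrix(x), y = beta_matrix(y),
    metadata = tibble(sample_id = sample_ids, family_id = family_ids,
                      outcome = outcome),
    truth = tibble(probe_id = probe_ids, class = cls, mu_x = mu_x,
                   mu_y = mu_y, intercept = intercept, slope = slope,
                   sample_sd = tau, offset = off, uncoupled = uncoupled,
                   outcome_effect = outcome_effect,
                   frac_truncated = frac_trunc),
    config = cfg
  ) |> structure(class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("<synthetic_pair> %d samples x %d probes (seed %d)\n",
              nrow(x$x), ncol(x$x), x$config$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Invert a beta matrix into a synthetic intensity set
#'
#' Builds methylated/unmethylated signals whose beta computation reproduces
#' the input exactly: with per-cell total signal `D` (the denominator
#' `M + U + offset`), `M = beta * D` and `U = D - offset - M`. The total is
#' raised per cell where needed so the unmethylated signal stays
#' nonnegative for betas near 1. Detection p-values and bead counts are
#' drawn with configurable failure rates (failing cells get detection p 0.5
#' and bead count 2); with zero failure rates every detection p is 0 and
#' every bead count 30.
#'
#' @param beta A `beta_matrix` with values strictly below 1.
#' @param total_signal Baseline total signal `M + U + offset`, default 10000.
#' @param offset Beta-formula offset, default 100.
#' @param detection_fail_rate,bead_fail_rate Per-cell failure probabilities.
#' @param seed Seed for the failure draws.
#' @return An [intensity_set()] satisfying
#'   `compute_beta(., offset) == beta` to within 1e-9.
#' @export
generate_intensity_set <- function(beta, total_signal = 10000, offset = 100,
                                   detection_fail_rate = 0,
                                   bead_fail_rate = 0, seed = 1) {
  beta <- validate_beta_matrix(beta)
  if (total_signal <= 0) abort("`total_signal` must be positive.")
  b <- unclass(beta)
  if (any(b >= 1, na.rm = TRUE)) {
    abort("Betas must be strictly below 1 to invert the intensity formula.")
  }
  d <- pmax(total_signal, 2 * offset / (1 - b))
  m <- b * d
  u <- d - offset - m
  m[is.na(b)] <- 0; u[is.na(b)] <- 0
  withr::with_seed(seed, {
    det_fail <- matrix(rbinom(length(b), 1, detection_fail_rate) == 1,
                       nrow(b), ncol(b))
    bead_fail <- matrix(rbinom(length(b), 1, bead_fail_rate) == 1,
                        nrow(b), ncol(b))
  })
  detection_p <- matrix(0, nrow(b), ncol(b), dimnames = dimnames(b))
  detection_p[det_fail] <- 0.5
  bead_count <- matrix(30L, nrow(b), ncol(b), dimnames = dimnames(b))
  bead_count[bead_fail] <- 2L
  dimnames(m) <- dimnames(b); dimnames(u) <- dimnames(b)
  intensity_set(m, u, detection_p = detection_p, bead_count = bead_count)
}

#' Write a synthetic pair to disk
#'
#' Writes the surrogate and target matrices in the package TSV dialect,
#' the metadata as TSV, and a manifest JSON recording the full generating
#' configuration and seed.
#'
#' @param pair A `synthetic_pair`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "synthetic_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    x = file.path(dir, "surrogate.tsv"),
    y = file.path(dir, "target.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_beta_matrix(pair$x, paths[["x"]])
  write_beta_matrix(pair$y, paths[["y"]])
  readr::write_tsv(pair$metadata, paths[["metadata"]], progress = FALSE)
  readr::write_tsv(pair$truth, paths[["truth"]], progress = FALSE)
  jsonlite::write_json(unclass(pair$config), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
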