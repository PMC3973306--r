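#' Quality thresholds for masking and sample QC
#'
#' Bundles the masking rules applied to raw measurements: a cell is masked
#' (set missing) when its detection p-value strictly exceeds
#' `detection_p_max` or its bead count is strictly below `min_bead_count`;
#' a sample is dropped when its fraction of missing probes strictly exceeds
#' `max_missing_fraction_per_sample`. All inequalities are strict, matching
#' the usual array-QC phrasing ("P > 0.01", "beads < 3", "> 20% missing").
#'
#' @param detection_p_max Detection p-value ceiling, in (0, 1). 0.05 is the
#'   usual 27k setting, 0.01 the 450k setting.
#' @param min_bead_count Minimum bead count (default 3); 0 disables.
#' @param max_missing_fraction_per_sample Sample-level missingness ceiling in
#'   (0, 1\], default 0.20.
#' @param snp_filter Whether SNP-flagged probes should be removed downstream.
#' @return A list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(detection_p_max = 0.01, min_bead_count = 3,
                               max_missing_fraction_per_sample = 0.20,
                               snp_filter = TRUE) {
  if (!(detection_p_max > 0 && detection_p_max < 1)) {
    abort("`detection_p_max` must lie in (0, 1).")
  }
  if (min_bead_count < 0) abort("`min_bead_count` must be >= 0.")
  if (!(max_missing_fraction_per_sample > 0 &&
        max_missing_fraction_per_sample <= 1)) {
    abort("`max_missing_fraction_per_sample` must lie in (0, 1].")
  }
  structure(
    list(detection_p_max = detection_p_max,
         min_bead_count = as.integer(min_bead_count),
         max_missing_fraction_per_sample = max_missing_fraction_per_sample,
         snp_filter = isTRUE(snp_filter)),
    class = "quality_thresholds"
  )
}

#' Mask low-quality measurements
#'
#' Sets beta cells missing where the detection p-value strictly exceeds the
#' threshold or the bead count is strictly below the minimum; all other cells
#' are unchanged. A cell at exactly the detection threshold is retained.
#'
#' @param beta A `beta_matrix`.
#' @param intensities The matching [intensity_set()] carrying `detection_p`
#'   and (optionally) `bead_count`.
#' @param thr A [quality_thresholds()] object.
#' @return The masked `beta_matrix`.
#' @export
mask_low_quality <- function(beta, intensities, thr = quality_thresholds()) {
  beta <- validate_beta_matrix(beta)
  stopifnot(inherits(intensities, "intensity_set"),
            inherits(thr, "quality_thresholds"))
  if (!identical(dim(beta), dim(intensities$methylated))) {
    abort("`beta` and `intensities` must share dimensions.")
  }
  b <- unclass(beta)
  if (!is.null(intensities$detection_p)) {
    b[!is.na(intensities$detection_p) &
        intensities$detection_p > thr$detection_p_max] <- NA_real_
  }
  if (!is.null(intensities$bead_count) && thr$min_bead_count > 0) {
    b[!is.na(intensities$bead_count) &
        intensities$bead_count < thr$min_bead_count] <- NA_real_
  }
  beta_matrix(b)
}

#' Drop samples with excessive missingness
#'
#' Removes samples whose fraction of missing probes strictly exceeds the
#' threshold (a sample at exactly the threshold is retained) and reports the
#' removed identifiers.
#'
#' @param beta A `beta_matrix`.
#' @param thr A [quality_thresholds()] object.
#' @param quiet Suppress the removal message.
#' @return The filtered `beta_matrix` with attribute `dropped_samples`.
#' @export
drop_failed_samples <- function(beta, thr = quality_thresholds(),
                                quiet = FALSE) {
  beta <- validate_beta_matrix(beta)
  frac <- rowMeans(is.na(beta))
  drop <- frac > thr$max_missing_fraction_per_sample
  if (all(drop)) abort("All samples exceed the missingness threshold.")
  if (any(drop) && !quiet) {
    inform(paste0("Dropped ", sum(drop), " sample(s) with > ",
                  100 * thr$max_missing_fraction_per_sample, "% missing probes: ",
                  paste(rownames(beta)[drop], collapse = ", ")))
  }
  out <- beta_matrix(unclass(beta)[!drop, , drop = FALSE])
  attr(out, "dropped_samples") <- rownames(beta)[drop]
  out
}

#' Quantile-normalize values across samples
#'
#' Forces every sample's value distribution onto a common reference built
#' from the across-sample mean of order statistics: after normalization the
#' sorted value vector of every (complete) sample is identical and ranks
#' within each sample are preserved. Missing values are tolerated; a sample's
#' non-missing values are mapped onto the reference by rank with linear
#' interpolation (the standard array practice, as implemented in
#' `limma::normalizeQuantiles`).
#'
#' Applied to probe intensities this is the usual between-array
#' normalization; the 27k profile pools methylated and unmethylated signals
#' into one set of rows before calling this function.
#'
#' @param values Numeric matrix, samples x features; `NA` allowed.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x features).")
  }
  if (nrow(values) < 2) abort("Quantile normalization needs >= 2 samples.")
  n_ok <- rowSums(!is.na(values))
  if (any(n_ok < 2)) {
    abort(paste0("Sample(s) with < 2 non-missing values: ",
                 paste(rownames(values)[n_ok < 2], collapse = ", ")))
  }
  out <- t(limma::normalizeQuantiles(t(unclass(values)), ties = TRUE))
  dimnames(out) <- dimnames(values)
  out
}

#' Align Infinium II betas onto the Infinium I distribution
#'
#' The two Illumina 450k probe chemistries produce systematically different
#' beta distributions. Within each functional category (island, shore, shelf,
#' ...) and each sample, type II betas are replaced by a monotone quantile
#' mapping onto the empirical distribution of that category's type I betas;
#' type I betas are left untouched. A type II value at the type II median
#' maps to the type I median.
#'
#' @param beta A `beta_matrix`.
#' @param ann Probe annotation (see [validate_probe_annotation()]) covering
#'   every probe in `beta`.
#' @return The aligned `beta_matrix`.
#' @export
align_typeII_to_typeI <- function(beta, ann) {
  beta <- validate_beta_matrix(beta)
  ann <- validate_probe_annotation(ann)
  missing_probes <- setdiff(colnames(beta), ann$probe_id)
  if (length(missing_probes) > 0) {
    abort(paste0("Probes without annotation: ",
                 paste(head(missing_probes, 5), collapse = ", ")))
  }
  ann <- ann[match(colnames(beta), ann$probe_id), ]
  b <- unclass(beta)
  for (cat in unique(ann$category)) {
    in_cat <- ann$category == cat
    idx_I <- which(in_cat & ann$design_type == "I")
    idx_II <- which(in_cat & ann$design_type == "II")
    if (length(idx_II) == 0) next
    if (length(idx_I) == 0) {
      abort(paste0("Category '", cat,
                   "' has Infinium II probes but no Infinium I reference probes."))
    }
    for (i in seq_len(nrow(b))) {
      ref <- b[i, idx_I]
      ref <- ref[!is.na(ref)]
      x2 <- b[i, idx_II]
      ok <- !is.na(x2)
      if (length(ref) == 0 || !any(ok)) next
      # mid-rank plotting positions keep the map symmetric: the type II
      # median lands on p = 0.5 and thus on the type I median
      p <- (rank(x2[ok], ties.method = "average") - 0.5) / sum(ok)
      b[i, idx_II[ok]] <- quantile(ref, probs = p, type = 7, names = FALSE)
    }
  }
  beta_matrix(pmin(pmax(b, 0), 1))
}

#' Remove SNP-overlapping probes
#'
#' Drops probes whose annotation flags overlap with a common SNP (or a SNP
#' within 10 bp of the interrogated site). Flags are taken from the
#' annotation table as given; no variant lookup is performed.
#'
#' @param beta A `beta_matrix`.
#' @param ann Probe annotation with `snp_flag`.
#' @param quiet Suppress the removal message.
#' @return The filtered `beta_matrix`.
#' @export
filter_snp_probes <- function(beta, ann, quiet = FALSE) {
  beta <- validate_beta_matrix(beta)
  ann <- validate_probe_annotation(ann)
  flagged <- ann$probe_id[ann$snp_flag %in% TRUE]
  drop <- colnames(beta) %in% flagged
  if (!quiet && any(drop)) {
    inform(paste0("Removed ", sum(drop), " SNP-flagged probe(s)."))
  }
  if (all(drop)) {
    warn("All probes are SNP-flagged; returning an empty probe set.")
  }
  beta_matrix(unclass(beta)[, !drop, drop = FALSE])
}

#' Extreme-probe filter specification
#'
#' Probes that are constitutively methylated or unmethylated in every sample
#' and tissue inflate between-tissue correlations without carrying
#' information about tissue-specific methylation. A probe is removed when its
#' pooled minimum beta exceeds `min_beta_threshold` (always high) or its
#' pooled maximum is below `max_beta_threshold` (always low). The standard
#' levels are (0.9, 0.1) and the stricter (0.8, 0.2).
#'
#' @param min_beta_threshold Removal threshold on the pooled minimum.
#' @param max_beta_threshold Removal threshold on the pooled maximum; must be
#'   strictly below `min_beta_threshold`.
#' @return A list of class `extreme_probe_filter`.
#' @export
extreme_probe_filter <- function(min_beta_threshold = 0.9,
                                 max_beta_threshold = 0.1) {
  if (!(max_beta_threshold >= 0 && max_beta_threshold < min_beta_threshold &&
        min_beta_threshold <= 1)) {
    abort("Need 0 <= max_beta_threshold < min_beta_threshold <= 1.")
  }
  structure(list(min_beta_threshold = min_beta_threshold,
                 max_beta_threshold = max_beta_threshold),
            class = "extreme_probe_filter")
}

#' Apply an extreme-probe filter across pooled matrices
#'
#' Pools every supplied beta matrix (all subjects and tissues), computes the
#' per-probe pooled minimum and maximum, and returns the identifiers of
#' retained probes: a probe is kept unless pooled min > `min_beta_threshold`
#' or pooled max < `max_beta_threshold`.
#'
#' @param matrices A single `beta_matrix` or a list of them sharing probes.
#' @param filter An [extreme_probe_filter()].
#' @return Character vector of retained probe ids, with attribute
#'   `removed` (the removed ids).
#' @export
filter_extreme_probes <- function(matrices, filter = extreme_probe_filter()) {
  if (inherits(matrices, "beta_matrix") || is.matrix(matrices)) {
    matrices <- list(matrices)
  }
  stopifnot(inherits(filter, "extreme_probe_filter"), length(matrices) > 0)
  matrices <- lapply(matrices, validate_beta_matrix)
  probes <- colnames(matrices[[1]])
  for (m in matrices[-1]) {
    if (!setequal(colnames(m), probes)) {
      abort("All matrices must share the same probe set.")
    }
  }
  pooled <- do.call(rbind, lapply(matrices, function(m) {
    unclass(m)[, probes, drop = FALSE]
  }))
  if (all(is.na(pooled))) abort("Empty pool: no non-missing beta values.")
  all_na <- colSums(!is.na(pooled)) == 0
  if (any(all_na)) {
    warn(paste0(sum(all_na), " probe(s) with no data excluded from retention."))
  }
  pmin_ <- suppressWarnings(apply(pooled, 2, min, na.rm = TRUE))
  pmax_ <- suppressWarnings(apply(pooled, 2, max, na.rm = TRUE))
  remove <- all_na | pmin_ > filter$min_beta_threshold |
    pmax_ < filter$max_beta_threshold
  kept <- probes[!remove]
  attr(kept, "removed") <- probes[remove]
  kept
}

#' Normalize a 27k-profile study from raw intensities
#'
#' The 27k chain: quantile-normalize all methylated and unmethylated probe
#' intensities together across samples, recompute beta as
#' `M / (M + U + offset)`, then mask cells with detection p strictly above
#' the threshold (0.05 for this profile; there is no bead-count filter on
#' 27k inputs).
#'
#' @param intensities An [intensity_set()].
#' @param thr A [quality_thresholds()]; default uses `detection_p_max = 0.05`
#'   and no bead filter.
#' @param offset Beta offset, default 100.
#' @return A masked, normalized `beta_matrix`.
#' @export
normalize_27k <- function(intensities,
                          thr = quality_thresholds(detection_p_max = 0.05,
                                                   min_bead_count = 0),
                          offset = 100) {
  stopifnot(inherits(intensities, "intensity_set"))
  m <- intensities$methylated
  u <- intensities$unmethylated
  pooled <- cbind(m, u)  # samples x (2m features): all probes together
  normed <- quantile_normalize(pooled)
  m_n <- normed[, seq_len(ncol(m)), drop = FALSE]
  u_n <- normed[, ncol(m) + seq_len(ncol(u)), drop = FALSE]
  dimnames(m_n) <- dimnames(m); dimnames(u_n) <- dimnames(u)
  norm_set <- intensity_set(m_n, u_n, detection_p = intensities$detection_p)
  mask_low_quality(compute_beta(norm_set, offset = offset), norm_set, thr)
}

#' Normalize a 450k-profile study
#'
#' A simplified two-step equivalent of the usual 450k pipeline, consuming
#' betas (background and color-bias correction are accepted as pre-applied
#' or skipped; this is recorded in the returned log): mask cells with
#' detection p > 0.01 or beads < 3, drop samples with > 20% missing probes,
#' remove SNP-flagged probes, sample-wise quantile normalization, then the
#' per-category Infinium II-to-I quantile alignment.
#'
#' @param beta A `beta_matrix` (betas as exported, or from [compute_beta()]).
#' @param intensities Optional [intensity_set()] supplying `detection_p` and
#'   `bead_count` for masking; skipped when `NULL`.
#' @param ann Probe annotation (design type, category, SNP flag).
#' @param thr A [quality_thresholds()] with the 450k defaults.
#' @param quantile_normalize_betas Apply across-sample quantile normalization
#'   to the beta matrix before the type II alignment (default `TRUE`).
#' @return A normalized `beta_matrix` with attribute `log`, a character
#'   vector describing the steps applied.
#' @export
normalize_450k <- function(beta, intensities = NULL, ann,
                           thr = quality_thresholds(detection_p_max = 0.01,
                                                    min_bead_count = 3),
                           quantile_normalize_betas = TRUE) {
  log <- character()
  beta <- validate_beta_matrix(beta)
  log <- c(log, "background/color-bias correction: accepted as pre-applied or skipped")
  if (!is.null(intensities)) {
    beta <- mask_low_quality(beta, intensities, thr)
    log <- c(log, sprintf("masked cells with detection p > %g or beads < %d",
                          thr$detection_p_max, thr$min_bead_count))
  }
  beta <- drop_failed_samples(beta, thr, quiet = TRUE)
  ndrop <- length(attr(beta, "dropped_samples"))
  log <- c(log, sprintf("dropped %d sample(s) with > %g%% missing probes",
                        ndrop, 100 * thr$max_missing_fraction_per_sample))
  if (thr$snp_filter) {
    before <- ncol(beta)
    beta <- filter_snp_probes(beta, ann, quiet = TRUE)
    log <- c(log, sprintf("removed %d SNP-flagged probe(s)", before - ncol(beta)))
  }
  if (quantile_normalize_betas) {
    beta <- beta_matrix(pmin(pmax(quantile_normalize(unclass(beta)), 0), 1))
    log <- c(log, "quantile-normalized betas across samples")
  }
  beta <- align_typeII_to_typeI(beta, ann)
  log <- c(log, "aligned Infinium II betas onto type I distributions per category")
  attr(beta, "log") <- log
  beta
}
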