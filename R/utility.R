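# Downstream-utility analyses: does calibration make the surrogate tissue
# more useful for the epidemiological question? Three views: per-probe
# outcome association, effect-size bias against the target-tissue gold
# standard, and hierarchical clustering of samples.

#' Per-probe association between methylation and a binary outcome
#'
#' Fits, for every probe, the simple linear regression
#' `methylation ~ outcome` with a binary case/control regressor. For a
#' binary regressor the coefficient is exactly the case-minus-control mean
#' difference; the standard error is the usual OLS one. Computed in closed
#' form across all probes.
#'
#' @param beta A `beta_matrix`.
#' @param outcome Binary vector (0/1), either named by sample id or in the
#'   row order of `beta`; both outcome groups need at least 2 samples.
#' @return A tibble of class `association_result` with columns `probe_id`,
#'   `effect`, `se`, `statistic`, `n`, `n_case`, `n_control`.
#' @export
associate_outcome <- function(beta, outcome) {
  beta <- validate_beta_matrix(beta)
  if (!is.null(names(outcome))) {
    missing_ids <- setdiff(rownames(beta), names(outcome))
    if (length(missing_ids) > 0) {
      abort(paste0("Samples without outcome: ", paste(missing_ids, collapse = ", ")))
    }
    outcome <- outcome[rownames(beta)]
  }
  if (length(outcome) != nrow(beta)) {
    abort("`outcome` length must match the number of samples.")
  }
  if (!all(outcome %in% c(0, 1))) abort("`outcome` must be binary 0/1.")
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 < 2 || n0 < 2) {
    abort(sprintf("Each outcome group needs >= 2 samples (got %d cases, %d controls).",
                  n1, n0))
  }
  b <- unclass(beta)
  ok <- !is.na(b)
  case <- outcome == 1
  n1j <- colSums(ok[case, , drop = FALSE])
  n0j <- colSums(ok[!case, , drop = FALSE])
  mean1 <- colSums(ifelse(ok, b, 0)[case, , drop = FALSE]) / pmax(n1j, 1)
  mean0 <- colSums(ifelse(ok, b, 0)[!case, , drop = FALSE]) / pmax(n0j, 1)
  effect <- mean1 - mean0
  # residual variance of the two-group model, df = n - 2
  ss1 <- colSums((sweep(ifelse(ok, b, 0)[case, , drop = FALSE], 2, mean1))^2 *
                   ok[case, , drop = FALSE])
  ss0 <- colSums((sweep(ifelse(ok, b, 0)[!case, , drop = FALSE], 2, mean0))^2 *
                   ok[!case, , drop = FALSE])
  nj <- n1j + n0j
  s2 <- (ss1 + ss0) / pmax(nj - 2, 1)
  se <- sqrt(s2 * (1 / pmax(n1j, 1) + 1 / pmax(n0j, 1)))
  bad <- n1j < 2 | n0j < 2
  effect[bad] <- NA_real_; se[bad] <- NA_real_
  out <- tibble(probe_id = colnames(b), effect = unname(effect),
                se = unname(se), statistic = unname(effect / se),
                n = unname(as.integer(nj)), n_case = unname(as.integer(n1j)),
                n_control = unname(as.integer(n0j)))
  class(out) <- c("association_result", class(out))
  out
}

#' Effect-size bias comparison against the target-tissue gold standard
#'
#' Taking the target-tissue association effects as truth, compares the
#' absolute bias of effects estimated from raw surrogate methylation with
#' the bias of effects estimated from calibrated (predicted-target)
#' methylation, probe by probe. Reports the fraction of probes where the
#' calibrated estimate is strictly less biased, together with tie and worse
#' counts.
#'
#' @param truth,raw,calibrated `association_result` tibbles (or data frames
#'   with `probe_id` and `effect`) over identical probe sets: target tissue,
#'   raw surrogate, and calibrated surrogate respectively.
#' @return A list of class `effect_bias_comparison`: `fraction_better`,
#'   `n_better`, `n_ties`, `n_worse`, `n_compared`, and the `per_probe`
#'   tibble of absolute biases.
#' @export
effect_bias_comparison <- function(truth, raw, calibrated) {
  grab <- function(d, label) {
    if (!all(c("probe_id", "effect") %in% names(d))) {
      abort(paste0("`", label, "` needs columns probe_id and effect."))
    }
    setNames(d$effect, d$probe_id)
  }
  e_t <- grab(truth, "truth"); e_r <- grab(raw, "raw")
  e_c <- grab(calibrated, "calibrated")
  if (!setequal(names(e_t), names(e_r)) || !setequal(names(e_t), names(e_c))) {
    abort("Probe sets of truth, raw and calibrated results must match.")
  }
  ids <- names(e_t)
  per_probe <- tibble(
    probe_id = ids,
    bias_raw = abs(e_r[ids] - e_t[ids]),
    bias_calibrated = abs(e_c[ids] - e_t[ids])
  )
  cmp <- per_probe[stats::complete.cases(per_probe), ]
  n_better <- sum(cmp$bias_calibrated < cmp$bias_raw)
  n_ties <- sum(cmp$bias_calibrated == cmp$bias_raw)
  n_worse <- sum(cmp$bias_calibrated > cmp$bias_raw)
  structure(list(fraction_better = n_better / nrow(cmp),
                 n_better = n_better, n_ties = n_ties, n_worse = n_worse,
                 n_compared = nrow(cmp), per_probe = per_probe),
            class = "effect_bias_comparison")
}

#' @export
print.effect_bias_comparison <- function(x, ...) {
  cat(sprintf(
    "<effect_bias_comparison> calibrated less biased at %.1f%% of %d probes (%d ties, %d worse)\n",
    100 * x$fraction_better, x$n_compared, x$n_ties, x$n_worse))
  invisible(x)
}

#' Hierarchical clustering of samples from a beta matrix
#'
#' Agglomerative clustering of samples on Euclidean distance over complete
#' probes (probes with any missing value are excluded and counted). Samples
#' are ordered lexicographically by id before clustering so the result is
#' deterministic, including among tied merge distances.
#'
#' @param beta A `beta_matrix` with >= 2 samples.
#' @param distance Distance metric; `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"`, or `"ward"`
#'   (Ward's D2).
#' @return An object of class `sample_dendrogram` wrapping the `hclust`
#'   tree, with `n_probes_used` / `n_probes_dropped`.
#' @export
cluster_samples <- function(beta, distance = "euclidean",
                            linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance, "euclidean")
  linkage <- match.arg(linkage)
  beta <- validate_beta_matrix(beta)
  if (nrow(beta) < 2) abort("Clustering needs >= 2 samples.")
  b <- unclass(beta)[order(rownames(beta)), , drop = FALSE]
  complete <- colSums(is.na(b)) == 0
  if (!any(complete)) abort("No probe is complete across all samples.")
  d <- dist(b[, complete, drop = FALSE], method = distance)
  hc <- hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(hclust = hc, distance = distance, linkage = linkage,
                 n_probes_used = sum(complete),
                 n_probes_dropped = sum(!complete)),
            class = "sample_dendrogram")
}

#' @export
print.sample_dendrogram <- function(x, ...) {
  cat(sprintf("<sample_dendrogram> %d samples, %s/%s linkage, %d probes (%d dropped)\n",
              length(x$hclust$labels), x$distance, x$linkage,
              x$n_probes_used, x$n_probes_dropped))
  invisible(x)
}

#' Serialize a sample dendrogram as a Newick string
#'
#' @param dend A `sample_dendrogram` (or `hclust`).
#' @param path Optional file path; when given, the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
as_newick <- function(dend, path = NULL) {
  hc <- if (inherits(dend, "sample_dendrogram")) dend$hclust else dend
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Cophenetic correlation between two sample dendrograms
#'
#' Pearson correlation between the cophenetic distance matrices of two trees
#' over their shared samples: a scale-free measure of how similar two
#' clusterings of the same samples are.
#'
#' @param a,b `sample_dendrogram` objects over the same samples.
#' @return Scalar correlation.
#' @export
cophenetic_correlation <- function(a, b) {
  stopifnot(inherits(a, "sample_dendrogram"), inherits(b, "sample_dendrogram"))
  da <- as.matrix(cophenetic(a$hclust))
  db <- as.matrix(cophenetic(b$hclust))
  ids <- intersect(rownames(da), rownames(db))
  if (length(ids) < 3) abort("Need >= 3 shared samples.")
  da <- da[ids, ids]; db <- db[ids, ids]
  lower <- lower.tri(da)
  cor(da[lower], db[lower])
}
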