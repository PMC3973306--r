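# Accuracy metrics. R-squared throughout this package is the squared
# Pearson correlation between two beta vectors (per sample across probes, or
# per probe across samples) -- not 1 - SSE/SST. The two differ for biased
# predictions: a prediction shifted by a constant keeps R-squared = 1 while
# its MAE reports the shift, which is why both metrics are always reported
# together.

.paired_metric <- function(truth, pred, fun, min_pairs) {
  ok <- !is.na(truth) & !is.na(pred)
  n <- sum(ok)
  if (n < min_pairs) {
    return(structure(NA_real_, reason = "too_few_pairs", n = n))
  }
  fun(truth[ok], pred[ok], n)
}

#' Squared Pearson correlation between paired beta vectors
#'
#' Computed over pairwise-complete entries. Undefined (returned as `NA` with
#' a `reason` attribute) when fewer than 3 pairs remain or either vector is
#' constant. Note that a perfectly anticorrelated prediction also scores 1;
#' MAE is the metric that distinguishes it.
#'
#' @param truth,pred Paired numeric vectors (a sample's row across probes,
#'   or a probe's column across samples).
#' @return Scalar in \[0, 1\] or `NA` with attributes `reason`, `n`.
#' @export
sample_r2 <- function(truth, pred) {
  .paired_metric(truth, pred, function(t, p, n) {
    if (sd(t) == 0 || sd(p) == 0) {
      return(structure(NA_real_, reason = "constant_vector", n = n))
    }
    structure(cor(t, p)^2, n = n)
  }, min_pairs = 3)
}

#' Mean absolute error between paired beta vectors
#'
#' Mean of `|truth - pred|` over pairwise-complete entries; requires at
#' least one pair.
#'
#' @inheritParams sample_r2
#' @return Nonnegative scalar, or `NA` with a `reason` attribute.
#' @export
sample_mae <- function(truth, pred) {
  .paired_metric(truth, pred, function(t, p, n) {
    structure(mean(abs(t - p)), n = n)
  }, min_pairs = 1)
}

#' @rdname sample_r2
#' @export
probe_r2 <- sample_r2

#' @rdname sample_mae
#' @export
probe_mae <- sample_mae

#' Build an accuracy report from a truth/prediction pair
#'
#' Computes per-sample (across probes) and per-probe (across samples)
#' squared correlation and mean absolute error, the per-probe target-tissue
#' standard deviation, overall means, and the count of predictions outside
#' \[0, 1\]. Samples or probes failing the metric minimums appear with `NA`
#' and a reason code rather than being silently excluded.
#'
#' @param truth Target `beta_matrix`.
#' @param pred Prediction matrix with identical dimnames.
#' @param method Label stored on the report.
#' @return A list of class `accuracy_report` with tibbles `per_sample`,
#'   `per_probe`, `overall`.
#' @export
accuracy_report <- function(truth, pred, method = "LM") {
  truth <- validate_beta_matrix(truth)
  if (!identical(dimnames(truth), dimnames(unclass(pred)))) {
    abort("`truth` and `pred` must share dimnames.")
  }
  tm <- unclass(truth); pm <- unclass(pred)
  row_stats <- function(i) {
    r2 <- sample_r2(tm[i, ], pm[i, ]); mae <- sample_mae(tm[i, ], pm[i, ])
    tibble(sample_id = rownames(tm)[i],
           r2 = as.numeric(r2), mae = as.numeric(mae),
           n_pairs = attr(mae, "n") %||% attr(r2, "n"),
           reason = attr(r2, "reason") %||% NA_character_)
  }
  col_stats <- function(j) {
    r2 <- probe_r2(tm[, j], pm[, j]); mae <- probe_mae(tm[, j], pm[, j])
    tibble(probe_id = colnames(tm)[j],
           r2 = as.numeric(r2), mae = as.numeric(mae),
           target_sd = sd(tm[, j], na.rm = TRUE),
           n_pairs = attr(mae, "n") %||% attr(r2, "n"),
           reason = attr(r2, "reason") %||% NA_character_)
  }
  per_sample <- purrr::map_dfr(seq_len(nrow(tm)), row_stats)
  per_probe <- purrr::map_dfr(seq_len(ncol(tm)), col_stats)
  n_oor <- attr(pred, "n_out_of_range") %||%
    sum(!is.na(pm) & (pm < 0 | pm > 1))
  overall <- tibble(
    method = method,
    mean_sample_r2 = mean(per_sample$r2, na.rm = TRUE),
    mean_sample_mae = mean(per_sample$mae, na.rm = TRUE),
    mean_probe_r2 = mean(per_probe$r2, na.rm = TRUE),
    mean_probe_mae = mean(per_probe$mae, na.rm = TRUE),
    n_out_of_range = n_oor
  )
  structure(list(per_sample = per_sample, per_probe = per_probe,
                 overall = overall, method = method),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> method %s\n", x$method))
  print(x$overall)
  invisible(x)
}

#' @export
tidy.accuracy_report <- function(x, level = c("probe", "sample"), ...) {
  level <- match.arg(level)
  if (level == "probe") x$per_probe else x$per_sample
}

#' @export
glance.accuracy_report <- function(x, ...) x$overall
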