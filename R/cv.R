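# Cross-validation harness. Folds either hold out one sample at a time or
# one whole family at a time; with related samples the family scheme is the
# one that keeps training and testing data completely independent.

#' Define a cross-validation scheme
#'
#' @param mode `"leave-one-family-out"` or `"leave-one-sample-out"`.
#' @param families Named character vector (or a metadata tibble with
#'   `sample_id` and `family_id`) mapping sample id to family id; required
#'   in family mode.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(mode = c("leave-one-family-out", "leave-one-sample-out"),
                      families = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(families)) {
    families <- setNames(as.character(families$family_id),
                         as.character(families$sample_id))
  }
  if (mode == "leave-one-family-out" && is.null(families)) {
    abort("Family mode requires a sample -> family map.")
  }
  structure(list(mode = mode, families = families), class = "cv_scheme")
}

# fold list: each element holds the test-sample ids
.cv_folds <- function(scheme, sample_ids) {
  if (scheme$mode == "leave-one-sample-out") {
    folds <- as.list(sample_ids)
    names(folds) <- sample_ids
  } else {
    fam <- scheme$families[sample_ids]
    if (anyNA(fam)) {
      abort(paste0("Samples without family id: ",
                   paste(sample_ids[is.na(fam)], collapse = ", ")))
    }
    folds <- split(sample_ids, fam)
  }
  if (length(folds) < 2) abort("Cross-validation needs at least 2 folds.")
  folds
}

#' Cross-validated cross-tissue calibration
#'
#' Runs the full calibration workflow under cross-validation: for each fold,
#' fits per-probe models on the training partition only, predicts the
#' held-out samples, assembles the complete predicted matrix, and computes
#' an accuracy report against the measured target matrix. No held-out
#' sample's target values ever influence its own prediction.
#'
#' @param x,y Aligned surrogate and target beta matrices.
#' @param scheme A [cv_scheme()].
#' @param method `"LM"`, `"SVR"`, or `"multiprobe-LM"`.
#' @param K Predictors per target probe (multi-probe method only).
#' @param target_probes Target probe ids (multi-probe method only; defaults
#'   to all probes).
#' @param clamp Truncate linear predictions into \[0, 1\] (the
#'   support-vector engine is always constrained to its training range).
#'   Default `FALSE`: out-of-range linear predictions are a documented
#'   property of the linear engine and are counted in the report.
#' @param min_pairs Minimum usable training pairs per probe and fold; probes
#'   below it are predicted `NA` for that fold.
#' @param quiet Suppress per-fold messages.
#' @return A list of class `cv_result`: `predictions` (samples x probes),
#'   `report` (an [accuracy_report()]), `folds`, `method`, `scheme`.
#' @export
cross_validate <- function(x, y, scheme, method = c("LM", "SVR", "multiprobe-LM"),
                           K = 5, target_probes = NULL, clamp = FALSE,
                           min_pairs = 3, quiet = TRUE) {
  method <- match.arg(method)
  x <- validate_beta_matrix(x); y <- validate_beta_matrix(y)
  if (!identical(dimnames(x), dimnames(y))) {
    abort("`x` and `y` must be aligned; see align_matrices().")
  }
  folds <- .cv_folds(scheme, rownames(x))
  xm <- unclass(x); ym <- unclass(y)
  out_probes <- if (method == "multiprobe-LM") {
    target_probes %||% colnames(y)
  } else colnames(y)
  pred <- matrix(NA_real_, nrow(xm), length(out_probes),
                 dimnames = list(rownames(xm), out_probes))
  n_oor <- 0
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(rownames(xm), test_ids)
    x_tr <- beta_matrix(xm[train_ids, , drop = FALSE])
    y_tr <- beta_matrix(ym[train_ids, , drop = FALSE])
    x_te <- beta_matrix(xm[test_ids, , drop = FALSE])
    if (method == "multiprobe-LM") {
      fit <- fit_multiprobe(x_tr, y_tr, target_probes = out_probes, K = K)
      p <- predict_multiprobe(fit, x_te, clamp = clamp)
    } else {
      fit <- fit_probe_models(x_tr, y_tr, method = method,
                              min_pairs = min_pairs, quiet = TRUE)
      p <- predict_matrix(fit, x_te, clamp = clamp)
    }
    n_oor <- n_oor + (attr(p, "n_out_of_range") %||% 0)
    pred[test_ids, ] <- p[test_ids, out_probes, drop = FALSE]
    if (!quiet) inform(sprintf("fold %d/%d: trained on %d samples, predicted %d",
                               f, length(folds), length(train_ids),
                               length(test_ids)))
  }
  attr(pred, "n_out_of_range") <- n_oor
  truth <- beta_matrix(ym[, out_probes, drop = FALSE])
  report <- accuracy_report(truth, pred, method = method)
  structure(list(predictions = pred, report = report, folds = folds,
                 method = method, scheme = scheme, clamp = clamp),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> method %s, %d folds (%s)\n", x$method,
              length(x$folds), x$scheme$mode))
  print(x$report$overall)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, level = c("probe", "sample"), ...) {
  tidy(x$report, level = match.arg(level))
}

#' @export
glance.cv_result <- function(x, ...) {
  dplyr::mutate(x$report$overall, n_folds = length(x$folds),
                scheme = x$scheme$mode)
}
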