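# Multi-probe extension: methylation at a CpG can correlate with other CpGs
# nearby or elsewhere in the genome, so the target probe's calibration may
# borrow strength from additional surrogate probes. The selection rule
# (same-id probe forced in, then largest absolute training correlation) is
# this package's own design: the extension itself, not the selection rule,
# is the established method.

#' Select surrogate predictor probes for one target probe
#'
#' Returns the same-id surrogate probe first, followed by the `K - 1`
#' surrogate probes whose training-data Pearson correlation with the target
#' vector has largest absolute value. Ties in |r| break deterministically by
#' lexicographic probe id.
#'
#' @param x Surrogate `beta_matrix` (training samples x probes).
#' @param y_j Numeric vector of target betas for the probe being modeled.
#' @param target_probe_id Id of the target probe; must exist in `x`.
#' @param K Total number of predictors (including the same-id probe); must
#'   satisfy `K < n - 1` where n is the number of training samples.
#' @return Character vector of K probe ids, same-id probe first.
#' @export
select_multiprobe_predictors <- function(x, y_j, target_probe_id, K) {
  x <- validate_beta_matrix(x)
  stopifnot(length(y_j) == nrow(x))
  if (!target_probe_id %in% colnames(x)) {
    abort(paste0("Target probe ", target_probe_id, " absent from surrogate matrix."))
  }
  n <- sum(!is.na(y_j))
  if (K >= n - 1) {
    abort(sprintf("K = %d predictors with n = %d samples is overparameterized (need K < n - 1).",
                  K, n))
  }
  if (K < 1) abort("K must be >= 1.")
  if (K == 1) return(target_probe_id)
  candidates <- setdiff(colnames(x), target_probe_id)
  r <- suppressWarnings(
    as.vector(cor(unclass(x)[, candidates, drop = FALSE], y_j,
                  use = "pairwise.complete.obs")))
  r[is.na(r)] <- 0
  ord <- order(-abs(r), candidates)
  c(target_probe_id, candidates[ord][seq_len(K - 1)])
}

# least squares on selected predictors with pairwise-complete rows; drops
# collinear predictors (NA coefficients from the pivoted QR) and refits.
.fit_multiprobe_one <- function(xm, y_j, predictors, target_probe_id) {
  keep <- predictors
  repeat {
    sub <- xm[, keep, drop = FALSE]
    cc <- complete.cases(sub) & !is.na(y_j)
    n <- sum(cc)
    if (n < length(keep) + 2) {
      return(list(predictors = keep, coefficients = NULL, n_obs = n,
                  flag = "insufficient_data"))
    }
    if (length(keep) == 1) {
      # exact nesting: a single predictor is the single-probe linear model
      m <- fit_linear_probe(sub[, 1], y_j, probe_id = target_probe_id)
      cf <- c("(Intercept)" = m$intercept, setNames(m$slope, keep))
      return(list(predictors = keep, coefficients = cf, n_obs = m$n_obs,
                  flag = m$flag))
    }
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, sub[cc, , drop = FALSE]),
                         y_j[cc])
    cf <- fit$coefficients
    bad <- names(cf)[is.na(cf)]
    if (length(bad) == 0) {
      return(list(predictors = keep, coefficients = cf, n_obs = n, flag = "ok"))
    }
    warn(paste0("Dropping collinear predictor(s) for ", target_probe_id, ": ",
                paste(bad, collapse = ", ")))
    keep <- setdiff(keep, bad)
  }
}

#' Fit multi-probe linear calibration models
#'
#' For each target probe, selects K surrogate predictors (see
#' [select_multiprobe_predictors()]) and fits multivariate least squares of
#' the target vector on them. With `K = 1` the coefficients coincide exactly
#' with the single-probe linear model.
#'
#' @param x,y Aligned surrogate and target beta matrices (training data).
#' @param target_probes Character vector of target probe ids (must be
#'   columns of `y`).
#' @param K Number of predictors per target probe, default 5; `K < n - 1`.
#' @return A list of class `multiprobe_model_set`.
#' @export
fit_multiprobe <- function(x, y, target_probes = colnames(y), K = 5) {
  x <- validate_beta_matrix(x); y <- validate_beta_matrix(y)
  if (!identical(rownames(x), rownames(y))) {
    abort("`x` and `y` must contain the same samples in the same order.")
  }
  absent <- setdiff(target_probes, colnames(y))
  if (length(absent) > 0) {
    abort(paste0("Target probes absent from `y`: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  if (K >= nrow(x) - 1) {
    abort(sprintf("K = %d with n = %d training samples is overparameterized.",
                  K, nrow(x)))
  }
  xm <- unclass(x); ym <- unclass(y)
  models <- lapply(target_probes, function(pid) {
    preds <- select_multiprobe_predictors(x, ym[, pid], pid, K)
    .fit_multiprobe_one(xm, ym[, pid], preds, pid)
  })
  names(models) <- target_probes
  structure(list(method = "multiprobe-LM", K = K, models = models,
                 target_probes = target_probes, n_train = nrow(x)),
            class = "multiprobe_model_set")
}

#' @export
print.multiprobe_model_set <- function(x, ...) {
  cat(sprintf("<multiprobe_model_set> K = %d predictors, %d target probes, %d training samples\n",
              x$K, length(x$target_probes), x$n_train))
  invisible(x)
}

#' @export
tidy.multiprobe_model_set <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    if (is.null(m$coefficients)) {
      return(tibble(predictor = NA_character_, coefficient = NA_real_,
                    n_obs = m$n_obs, flag = m$flag))
    }
    tibble(predictor = names(m$coefficients),
           coefficient = unname(m$coefficients),
           n_obs = m$n_obs, flag = m$flag)
  }, .id = "target_probe")
}

#' Predict target probes from a multi-probe model set
#'
#' @param models A `multiprobe_model_set`.
#' @param x_new Surrogate `beta_matrix` containing every selected predictor
#'   probe.
#' @param clamp Truncate predictions into \[0, 1\].
#' @return Matrix (samples x target probes) with attribute `n_out_of_range`.
#' @export
predict_multiprobe <- function(models, x_new, clamp = FALSE) {
  stopifnot(inherits(models, "multiprobe_model_set"))
  x_new <- validate_beta_matrix(x_new)
  xm <- unclass(x_new)
  need <- unique(unlist(lapply(models$models, `[[`, "predictors")))
  unknown <- setdiff(need, colnames(xm))
  if (length(unknown) > 0) {
    abort(paste0("Predictor probes absent from `x_new`: ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  pred <- matrix(NA_real_, nrow(xm), length(models$target_probes),
                 dimnames = list(rownames(xm), models$target_probes))
  for (pid in models$target_probes) {
    m <- models$models[[pid]]
    if (is.null(m$coefficients)) next
    design <- cbind(1, xm[, m$predictors, drop = FALSE])
    pred[, pid] <- as.vector(design %*% m$coefficients)
  }
  oor <- sum(!is.na(pred) & (pred < 0 | pred > 1))
  if (clamp) pred <- pmin(pmax(pred, 0), 1)
  attr(pred, "n_out_of_range") <- oor
  pred
}

#' @export
predict.multiprobe_model_set <- function(object, newdata, ...) {
  predict_multiprobe(object, newdata, ...)
}

#' Randomly select evaluation target probes for the multi-probe model
#'
#' The multi-probe extension is most interesting for probes with substantial
#' target-tissue variation but poor single-probe cross-tissue agreement.
#' Draws a uniform random sample (seeded, without replacement) of `count`
#' probes whose target-tissue standard deviation lies in `sd_range` and
#' whose raw cross-tissue R-squared is below `r2_max`. When fewer probes are
#' eligible than requested, all eligible probes are returned with a warning.
#'
#' @param y Target `beta_matrix`.
#' @param raw_r2 Named numeric vector of per-probe raw cross-tissue
#'   R-squared values (squared Pearson correlation between tissues, training
#'   data).
#' @param sd_range Length-2 numeric, inclusive bounds on target SD; default
#'   `c(0.1, 0.2)`.
#' @param r2_max Strict upper bound on raw R-squared, default 0.3.
#' @param count Number of probes to draw, default 1000.
#' @param seed Integer seed for the draw.
#' @return Character vector of probe ids.
#' @export
select_target_probes_for_multiprobe <- function(y, raw_r2,
                                                sd_range = c(0.1, 0.2),
                                                r2_max = 0.3, count = 1000,
                                                seed = 1) {
  y <- validate_beta_matrix(y)
  sds <- apply(unclass(y), 2, sd, na.rm = TRUE)
  r2 <- raw_r2[match(colnames(y), names(raw_r2))]
  eligible <- colnames(y)[!is.na(sds) & sds >= sd_range[1] & sds <= sd_range[2] &
                            !is.na(r2) & r2 < r2_max]
  if (length(eligible) <= count) {
    if (length(eligible) < count) {
      warn(sprintf("Only %d probes eligible (requested %d); returning all.",
                   length(eligible), count))
    }
    return(eligible)
  }
  withr::with_seed(seed, sample(eligible, count))
}
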