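# Per-probe cross-tissue calibration models.
#
# The calibration problem: for probe j, paired training betas (x_ij, y_ij)
# from surrogate and target tissue, learn y = f_j(x). Two engines:
#   LM  -- ordinary least squares y = a_j + b_j x (closed form),
#   SVR -- epsilon-insensitive support-vector regression, RBF kernel,
#          epsilon 0.1, cost 1, gamma 1/#predictors, standardized inputs
#          (the e1071 eps-regression defaults).

.svr_defaults <- function(n_predictors = 1) {
  list(epsilon = 0.1, cost = 1, gamma = 1 / n_predictors, scale = TRUE)
}

#' Fit the linear calibration model for one probe
#'
#' Ordinary least squares of target beta on surrogate beta:
#' slope = cov(x, y) / var(x), intercept = mean(y) - slope * mean(x),
#' computed over pairwise-complete observations. With a constant predictor
#' the slope is unidentifiable and the model falls back to intercept-only
#' (predicting mean(y)), flagged `"constant_x"`. Fewer than 3 complete pairs
#' yields a model flagged `"insufficient_data"` that predicts `NA`.
#'
#' @param x,y Numeric vectors of surrogate and target betas.
#' @param probe_id Optional identifier stored on the model.
#' @return A list of class `linear_probe_model` with elements `intercept`,
#'   `slope`, `n_obs`, `flag` (`"ok"`, `"constant_x"`, or
#'   `"insufficient_data"`).
#' @examples
#' fit_linear_probe(c(0.1, 0.2, 0.3), c(0.25, 0.45, 0.65))
#' @export
fit_linear_probe <- function(x, y, probe_id = NA_character_) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) {
    return(structure(list(probe_id = probe_id, intercept = NA_real_,
                          slope = NA_real_, n_obs = n,
                          flag = "insufficient_data"),
                     class = "linear_probe_model"))
  }
  xo <- x[ok]; yo <- y[ok]
  sxx <- sum((xo - mean(xo))^2)
  if (sxx == 0) {
    return(structure(list(probe_id = probe_id, intercept = mean(yo),
                          slope = 0, n_obs = n, flag = "constant_x"),
                     class = "linear_probe_model"))
  }
  slope <- sum((xo - mean(xo)) * (yo - mean(yo))) / sxx
  structure(list(probe_id = probe_id, intercept = mean(yo) - slope * mean(xo),
                 slope = slope, n_obs = n, flag = "ok"),
            class = "linear_probe_model")
}

#' Predict from a linear probe model
#'
#' Returns `intercept + slope * x_new`. Linear extrapolation can leave the
#' \[0, 1\] beta range; by default such values are returned unclamped (the
#' documented behavior of the linear engine) and counted in the
#' `n_out_of_range` attribute. Set `clamp = TRUE` to truncate into \[0, 1\].
#'
#' @param m A `linear_probe_model`.
#' @param x_new Numeric vector of surrogate betas.
#' @param clamp Truncate predictions into \[0, 1\]?
#' @return Numeric vector of predictions with attribute `n_out_of_range`.
#' @export
predict_linear_probe <- function(m, x_new, clamp = FALSE) {
  stopifnot(inherits(m, "linear_probe_model"))
  pred <- switch(m$flag,
    insufficient_data = rep(NA_real_, length(x_new)),
    constant_x = rep(m$intercept, length(x_new)) + 0 * x_new,  # keep NA in x
    m$intercept + m$slope * x_new
  )
  oor <- sum(!is.na(pred) & (pred < 0 | pred > 1))
  if (clamp) pred <- pmin(pmax(pred, 0), 1)
  attr(pred, "n_out_of_range") <- oor
  pred
}

#' @export
predict.linear_probe_model <- function(object, newdata, ...) {
  predict_linear_probe(object, newdata, ...)
}

#' Fit the support-vector calibration model for one probe
#'
#' Epsilon-insensitive support-vector regression of target on surrogate beta
#' with a radial-basis-function kernel and the reference defaults:
#' epsilon 0.1, cost 1, kernel width gamma = 1 / number of predictors, and
#' standardization of inputs and output before fitting (inverted at
#' prediction). The training-target range is recorded and predictions are
#' constrained to it (see [predict_svr_probe()]), giving the support-vector
#' engine its characteristic robustness to extrapolation that the linear
#' engine lacks. A constant target cannot be standardized and yields a
#' flagged constant model that predicts that constant.
#'
#' @param x,y Numeric vectors of paired surrogate and target betas.
#' @param probe_id Optional identifier.
#' @param epsilon,cost,gamma,scale Hyperparameters; defaults are the
#'   reference eps-regression defaults.
#' @param keep_data Store the training pairs on the model (needed for JSON
#'   serialization; default `TRUE`).
#' @return A list of class `svr_probe_model` with the fitted predictor,
#'   `training_y_range`, `n_obs`, `flag` and `hyperparameters`.
#' @export
fit_svr_probe <- function(x, y, probe_id = NA_character_,
                          epsilon = 0.1, cost = 1, gamma = 1, scale = TRUE,
                          keep_data = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  hyper <- list(epsilon = epsilon, cost = cost, gamma = gamma, scale = scale)
  base <- list(probe_id = probe_id, fit = NULL, constant = NA_real_,
               training_y_range = c(NA_real_, NA_real_), n_obs = n,
               flag = "ok", hyperparameters = hyper,
               train_x = if (keep_data) x[ok] else NULL,
               train_y = if (keep_data) y[ok] else NULL)
  if (n < 3) {
    base$flag <- "insufficient_data"
    return(structure(base, class = "svr_probe_model"))
  }
  xo <- x[ok]; yo <- y[ok]
  base$training_y_range <- range(yo)
  if (sd(yo) == 0 || sd(xo) == 0) {
    # constant target (or constant predictor): flat model within the tube
    base$flag <- if (sd(yo) == 0) "constant_y" else "constant_x"
    base$constant <- mean(yo)
    return(structure(base, class = "svr_probe_model"))
  }
  fit <- e1071::svm(x = matrix(xo, ncol = 1), y = yo, type = "eps-regression",
                    kernel = "radial", epsilon = epsilon, cost = cost,
                    gamma = gamma, scale = scale)
  base$fit <- fit
  structure(base, class = "svr_probe_model")
}

#' Predict from a support-vector probe model
#'
#' Applies the fitted predictor; by default predictions are constrained to
#' the training-target range `[min(train y), max(train y)]`, enforcing the
#' range property of the support-vector engine for any finite query,
#' including queries far outside the training predictor range.
#'
#' @param m An `svr_probe_model`.
#' @param x_new Numeric vector of surrogate betas (`NA` yields `NA`).
#' @param clamp_to_range Constrain predictions to the training-target range
#'   (default `TRUE`).
#' @return Numeric vector of predictions.
#' @export
predict_svr_probe <- function(m, x_new, clamp_to_range = TRUE) {
  stopifnot(inherits(m, "svr_probe_model"))
  if (m$flag == "insufficient_data") return(rep(NA_real_, length(x_new)))
  pred <- rep(NA_real_, length(x_new))
  ok <- !is.na(x_new)
  if (m$flag %in% c("constant_y", "constant_x")) {
    pred[ok] <- m$constant
  } else if (any(ok) && is.null(m$fit) && !is.null(m$expansion)) {
    # deserialized predictor: evaluate the RBF kernel expansion directly
    e <- m$expansion
    z <- (x_new[ok] - e$x_center) / e$x_scale
    raw <- vapply(z, function(zi) {
      sum(e$coefs * exp(-e$gamma * (zi - e$sv)^2)) - e$rho
    }, numeric(1))
    pred[ok] <- raw * e$y_scale + e$y_center
  } else if (any(ok)) {
    pred[ok] <- as.numeric(predict(m$fit, matrix(x_new[ok], ncol = 1)))
  }
  if (clamp_to_range && !anyNA(m$training_y_range)) {
    pred <- pmin(pmax(pred, m$training_y_range[1]), m$training_y_range[2])
  }
  pred
}

#' @export
predict.svr_probe_model <- function(object, newdata, ...) {
  predict_svr_probe(object, newdata, ...)
}

# Vectorized OLS over every probe of a pair of aligned matrices, with
# pairwise-complete observations. Returns per-probe intercept/slope/n/flag.
fit_lm_matrix <- function(x, y, min_pairs = 3) {
  w <- (!is.na(x)) & (!is.na(y))
  x0 <- ifelse(w, x, 0)
  y0 <- ifelse(w, y, 0)
  n <- colSums(w)
  sx <- colSums(x0)
  sy <- colSums(y0)
  sxx <- colSums(x0 * x0)
  sxy <- colSums(x0 * y0)
  vx <- sxx - sx^2 / pmax(n, 1)
  cxy <- sxy - sx * sy / pmax(n, 1)
  slope <- cxy / vx
  intercept <- sy / pmax(n, 1) - slope * sx / pmax(n, 1)
  flag <- rep("ok", ncol(x))
  const <- vx <= .Machine$double.eps * pmax(sxx, 1)
  flag[const] <- "constant_x"
  slope[const] <- 0
  intercept[const] <- (sy / pmax(n, 1))[const]
  insuf <- n < min_pairs
  flag[insuf] <- "insufficient_data"
  slope[insuf] <- NA_real_
  intercept[insuf] <- NA_real_
  tibble(probe_id = colnames(x), intercept = unname(intercept),
         slope = unname(slope), n_obs = unname(as.integer(n)), flag = flag)
}

#' Fit calibration models for every probe
#'
#' Fits one model per probe over the samples where both tissues are
#' non-missing (pairwise-complete). Probes with fewer than `min_pairs`
#' usable pairs, or a constant predictor, are flagged rather than silently
#' dropped. Training sets smaller than 10 samples trigger a warning: small
#' training sets leave both engines vulnerable to outliers.
#'
#' @param x Surrogate `beta_matrix` (samples x probes).
#' @param y Target `beta_matrix`, aligned with `x` (same samples and probes
#'   in the same order; see [align_matrices()]).
#' @param method `"LM"` or `"SVR"`.
#' @param min_pairs Minimum usable pairs per probe, default 3.
#' @param svr_control Optional named list overriding the SVR defaults
#'   (`epsilon`, `cost`, `gamma`, `scale`).
#' @param quiet Suppress messages.
#' @return A list of class `probe_model_set`.
#' @export
fit_probe_models <- function(x, y, method = c("LM", "SVR"), min_pairs = 3,
                             svr_control = list(), quiet = FALSE) {
  method <- match.arg(method)
  x <- validate_beta_matrix(x); y <- validate_beta_matrix(y)
  if (!identical(dimnames(x), dimnames(y))) {
    abort("`x` and `y` must be aligned (identical samples and probes); see align_matrices().")
  }
  if (nrow(x) < 10 && !quiet) {
    warn(paste0("Training set has only ", nrow(x),
                " samples; at least 10 are recommended for stable calibration."))
  }
  xm <- unclass(x); ym <- unclass(y)
  if (method == "LM") {
    coefs <- fit_lm_matrix(xm, ym, min_pairs = min_pairs)
    if (all(coefs$flag == "insufficient_data")) {
      abort("No probe has enough paired observations to fit a model.")
    }
    out <- list(method = "LM", coefficients = coefs, models = NULL,
                probe_ids = colnames(x), n_train = nrow(x),
                min_pairs = min_pairs)
  } else {
    ctrl <- modifyList(.svr_defaults(1), svr_control)
    models <- lapply(seq_len(ncol(xm)), function(j) {
      fit_svr_probe(xm[, j], ym[, j], probe_id = colnames(xm)[j],
                    epsilon = ctrl$epsilon, cost = ctrl$cost,
                    gamma = ctrl$gamma, scale = ctrl$scale)
    })
    names(models) <- colnames(xm)
    if (all(vapply(models, `[[`, "", "flag") == "insufficient_data")) {
      abort("No probe has enough paired observations to fit a model.")
    }
    out <- list(method = "SVR", coefficients = NULL, models = models,
                probe_ids = colnames(x), n_train = nrow(x),
                min_pairs = min_pairs, svr_control = ctrl)
  }
  structure(out, class = "probe_model_set")
}

#' @export
print.probe_model_set <- function(x, ...) {
  cat(sprintf("<probe_model_set> method %s: %d probes, %d training samples\n",
              x$method, length(x$probe_ids), x$n_train))
  invisible(x)
}

#' Tidy a probe model set
#'
#' @param x A `probe_model_set`.
#' @param ... Unused.
#' @return One row per probe. For the linear engine: `intercept`, `slope`,
#'   `n_obs`, `flag`. For the support-vector engine: the training-target
#'   range, support-vector count, `n_obs`, `flag`.
#' @export
tidy.probe_model_set <- function(x, ...) {
  if (x$method == "LM") return(x$coefficients)
  purrr::map_dfr(x$models, function(m) {
    tibble(probe_id = m$probe_id,
           y_min = m$training_y_range[1], y_max = m$training_y_range[2],
           n_support = if (is.null(m$fit)) NA_integer_ else m$fit$tot.nSV,
           n_obs = m$n_obs, flag = m$flag)
  })
}

#' @export
glance.probe_model_set <- function(x, ...) {
  flags <- if (x$method == "LM") x$coefficients$flag else
    vapply(x$models, `[[`, "", "flag")
  tibble(method = x$method, n_probes = length(x$probe_ids),
         n_train = x$n_train, n_flagged = sum(flags != "ok"))
}

#' Predict a target-tissue matrix from surrogate betas
#'
#' Applies the per-probe calibration models elementwise to a new surrogate
#' matrix. Missing surrogate cells yield missing predictions. For the linear
#' engine, predictions outside \[0, 1\] are preserved by default but counted
#' (attribute `n_out_of_range`); `clamp = TRUE` truncates them. The
#' support-vector engine is always constrained to each probe's
#' training-target range.
#'
#' @param models A `probe_model_set`.
#' @param x_new Surrogate `beta_matrix` whose probes are all present in the
#'   model set (an unknown probe raises an error naming the ids).
#' @param clamp Truncate linear predictions into \[0, 1\].
#' @return Numeric matrix of predictions (samples x probes) with attribute
#'   `n_out_of_range`. Not a `beta_matrix` when unclamped values leave
#'   \[0, 1\].
#' @export
predict_matrix <- function(models, x_new, clamp = FALSE) {
  stopifnot(inherits(models, "probe_model_set"))
  x_new <- validate_beta_matrix(x_new)
  unknown <- setdiff(colnames(x_new), models$probe_ids)
  if (length(unknown) > 0) {
    abort(paste0("Probes absent from the model set: ",
                 paste(head(unknown, 10), collapse = ", "),
                 if (length(unknown) > 10) " ..." else ""))
  }
  xm <- unclass(x_new)
  if (models$method == "LM") {
    cf <- models$coefficients
    idx <- match(colnames(xm), cf$probe_id)
    a <- cf$intercept[idx]; b <- cf$slope[idx]
    pred <- sweep(sweep(xm, 2, b, `*`), 2, a, `+`)
    cx <- cf$flag[idx] == "constant_x"
    if (any(cx)) pred[, cx] <- rep(a[cx], each = nrow(xm)) + 0 * xm[, cx]
    ins <- cf$flag[idx] == "insufficient_data"
    if (any(ins)) pred[, ins] <- NA_real_
  } else {
    pred <- xm * NA_real_
    for (j in seq_len(ncol(xm))) {
      pred[, j] <- predict_svr_probe(models$models[[colnames(xm)[j]]], xm[, j])
    }
  }
  oor <- sum(!is.na(pred) & (pred < 0 | pred > 1))
  if (clamp) pred <- pmin(pmax(pred, 0), 1)
  dimnames(pred) <- dimnames(xm)
  attr(pred, "n_out_of_range") <- oor
  pred
}

#' @export
predict.probe_model_set <- function(object, newdata, ...) {
  predict_matrix(object, newdata, ...)
}
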