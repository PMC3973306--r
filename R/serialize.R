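# Versioned JSON model container, so a model trained on study A can be
# applied to study B in a later session or another machine. Linear models
# store their coefficients; support-vector models store the fitted RBF
# kernel expansion (support vectors, dual coefficients, rho, scaling) so
# the deserialized predictor reproduces the trained one exactly, plus the
# training pairs and hyperparameters for provenance.

.container_version <- 1L

#' Write a fitted model set to a JSON container
#'
#' @param models A `probe_model_set` or `multiprobe_model_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_set <- function(models, path) {
  if (inherits(models, "probe_model_set")) {
    payload <- list(
      container_version = .container_version,
      software_version = as.character(packageVersion("methcal")),
      method = models$method, n_train = models$n_train,
      min_pairs = models$min_pairs
    )
    if (models$method == "LM") {
      payload$coefficients <- models$coefficients
    } else {
      payload$hyperparameters <- models$svr_control
      payload$probes <- lapply(models$models, function(m) {
        entry <- list(probe_id = m$probe_id, flag = m$flag, n_obs = m$n_obs,
                      constant = m$constant,
                      training_y_range = m$training_y_range,
                      train_x = m$train_x, train_y = m$train_y)
        if (!is.null(m$fit)) {
          f <- m$fit
          entry$expansion <- list(
            sv = as.numeric(f$SV), coefs = as.numeric(f$coefs), rho = f$rho,
            gamma = f$gamma,
            x_center = as.numeric(f$x.scale$"scaled:center" %||% 0),
            x_scale = as.numeric(f$x.scale$"scaled:scale" %||% 1),
            y_center = as.numeric(f$y.scale$"scaled:center" %||% 0),
            y_scale = as.numeric(f$y.scale$"scaled:scale" %||% 1))
        }
        entry
      })
    }
  } else if (inherits(models, "multiprobe_model_set")) {
    payload <- list(
      container_version = .container_version,
      software_version = as.character(packageVersion("methcal")),
      method = models$method, n_train = models$n_train, K = models$K,
      probes = lapply(models$models, function(m) {
        list(predictors = m$predictors,
             coefficients = as.list(m$coefficients),
             n_obs = m$n_obs, flag = m$flag)
      })
    )
    names(payload$probes) <- models$target_probes
  } else {
    abort("`models` must be a probe_model_set or multiprobe_model_set.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read a fitted model set from a JSON container
#'
#' @param path Path written by [write_model_set()].
#' @return The reconstructed model set; support-vector predictors are
#'   rebuilt from their stored kernel expansions and evaluate identically
#'   to the originals.
#' @export
read_model_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  if (is.null(payload$method)) abort(paste0("Not a model container: ", path))
  if (payload$method == "LM") {
    coefs <- as_tibble(payload$coefficients)
    structure(list(method = "LM", coefficients = coefs, models = NULL,
                   probe_ids = coefs$probe_id, n_train = payload$n_train,
                   min_pairs = payload$min_pairs),
              class = "probe_model_set")
  } else if (payload$method == "SVR") {
    ctrl <- payload$hyperparameters
    probes <- jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)$probes
    models <- lapply(probes, function(p) {
      m <- list(probe_id = p$probe_id, fit = NULL,
                constant = p$constant %||% NA_real_,
                training_y_range = unlist(p$training_y_range),
                n_obs = p$n_obs, flag = p$flag, hyperparameters = ctrl,
                train_x = unlist(p$train_x), train_y = unlist(p$train_y))
      if (!is.null(p$expansion)) {
        m$expansion <- lapply(p$expansion, unlist)
      }
      structure(m, class = "svr_probe_model")
    })
    names(models) <- vapply(probes, `[[`, "", "probe_id")
    structure(list(method = "SVR", coefficients = NULL, models = models,
                   probe_ids = names(models), n_train = payload$n_train,
                   min_pairs = payload$min_pairs, svr_control = ctrl),
              class = "probe_model_set")
  } else if (payload$method == "multiprobe-LM") {
    probes <- jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)$probes
    models <- lapply(probes, function(p) {
      cf <- unlist(p$coefficients)
      list(predictors = unlist(p$predictors), coefficients = cf,
           n_obs = p$n_obs, flag = p$flag)
    })
    structure(list(method = "multiprobe-LM", K = payload$K, models = models,
                   target_probes = names(models), n_train = payload$n_train),
              class = "multiprobe_model_set")
  } else {
    abort(paste0("Unknown model method: ", payload$method))
  }
}
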