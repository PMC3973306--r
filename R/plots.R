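# ggplot2 views of the result objects. Each autoplot() mirrors the figure a
# methylation analyst would draw by hand: accuracy against target-tissue
# variability, bin-density fractions, and the sample-size curve.

#' Plot per-probe accuracy against target-tissue variability
#'
#' Scatter of per-probe cross-validated R-squared (or MAE) against the
#' target-tissue standard deviation, with a smoothing curve. For MAE the
#' identity line marks one standard deviation: well-calibrated probes sit
#' below it.
#'
#' @param object A `cv_result` or `accuracy_report`.
#' @param metric `"r2"` or `"mae"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, metric = c("r2", "mae"), ...) {
  autoplot(object$report, metric = metric, ...)
}

#' @rdname autoplot.cv_result
#' @export
autoplot.accuracy_report <- function(object, metric = c("r2", "mae"), ...) {
  metric <- match.arg(metric)
  pp <- object$per_probe
  p <- ggplot2::ggplot(pp, ggplot2::aes(x = .data$target_sd,
                                        y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         na.rm = TRUE) +
    ggplot2::labs(x = "SD of methylation in target tissue",
                  y = if (metric == "r2") expression(R^2) else "Mean absolute error",
                  title = paste0("Probe-specific accuracy (", object$method, ")")) +
    ggplot2::theme_minimal()
  if (metric == "mae") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2)
  }
  p
}

#' Plot within-bin prediction fractions
#'
#' One panel of the bin-density diagnostic: for each bin of the measured
#' target value, the fraction of raw surrogate values and of each engine's
#' predictions that fall inside that bin's interval.
#'
#' @param data A tibble from [density_by_bin()].
#' @return A ggplot object.
#' @export
plot_density_by_bin <- function(data) {
  long <- data |>
    dplyr::select("bin", "lower", "upper",
                  dplyr::starts_with("frac_")) |>
    tidyr::pivot_longer(dplyr::starts_with("frac_"), names_to = "set",
                        names_prefix = "frac_", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$bin),
                                     y = .data$fraction,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge", na.rm = TRUE) +
    ggplot2::labs(x = "Bin of measured target methylation",
                  y = "Fraction of values inside the bin", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sample-size experiment
#'
#' Mean absolute prediction error on the held-out test set against training
#' sample size, one curve per engine.
#'
#' @param object A `sample_size_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_size_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$size, y = .data$mean_abs_error,
                               color = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Training sample size",
                  y = "Mean absolute prediction error", color = NULL) +
    ggplot2::theme_minimal()
}
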