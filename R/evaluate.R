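# Study-level evaluation summaries: raw between-tissue correlation under
# extreme-probe filters, accuracy stratified by target-tissue variability,
# the bin-density diagnostic, and the training-sample-size experiment.

#' Between-tissue correlation summary under extreme-probe filters
#'
#' For each supplied filter level, restricts both matrices to the retained
#' probes and computes the per-sample squared Pearson correlation between
#' the tissues, summarizing mean, min and max across samples together with
#' the number of probes removed. The conventional levels are no filter,
#' (0.9, 0.1) and (0.8, 0.2); constitutively methylated/unmethylated probes
#' inflate the unfiltered correlation.
#'
#' @param x,y Aligned beta matrices for the two tissues.
#' @param filters List of [extreme_probe_filter()] objects; `NULL` entries
#'   (or the default first entry) mean "all probes".
#' @return A tibble with one row per filter level.
#' @export
cross_tissue_correlation <- function(x, y,
                                     filters = list(NULL,
                                                    extreme_probe_filter(0.9, 0.1),
                                                    extreme_probe_filter(0.8, 0.2))) {
  x <- validate_beta_matrix(x); y <- validate_beta_matrix(y)
  if (!identical(dimnames(x), dimnames(y))) {
    abort("`x` and `y` must be aligned; see align_matrices().")
  }
  purrr::map_dfr(filters, function(f) {
    if (is.null(f)) {
      kept <- colnames(x); removed <- 0L
      label <- "all probes"
    } else {
      kept <- filter_extreme_probes(list(x, y), f)
      removed <- length(attr(kept, "removed"))
      label <- sprintf("min > %g or max < %g removed",
                       f$min_beta_threshold, f$max_beta_threshold)
    }
    xs <- unclass(x)[, kept, drop = FALSE]
    ys <- unclass(y)[, kept, drop = FALSE]
    r2 <- vapply(seq_len(nrow(xs)), function(i) {
      as.numeric(sample_r2(xs[i, ], ys[i, ]))
    }, numeric(1))
    tibble(filter = label,
           min_beta_threshold = if (is.null(f)) NA_real_ else f$min_beta_threshold,
           max_beta_threshold = if (is.null(f)) NA_real_ else f$max_beta_threshold,
           probes_retained = length(kept), probes_removed = removed,
           mean_r2 = mean(r2, na.rm = TRUE),
           min_r2 = suppressWarnings(min(r2, na.rm = TRUE)),
           max_r2 = suppressWarnings(max(r2, na.rm = TRUE)))
  })
}

#' Stratify prediction accuracy by target-tissue variability
#'
#' Probes with substantial methylation variation in the target tissue are
#' the ones a calibration model can meaningfully predict; probes with near
#'-zero variance have undefined correlation and an MAE floor set by
#' technical noise. Bins the per-probe report by target-tissue standard
#' deviation and summarizes mean R-squared, mean MAE, and the fraction of
#' probes whose MAE is below one target-tissue standard deviation.
#'
#' @param report An [accuracy_report()] (or `cv_result`).
#' @param breaks Bin edges for the target SD axis; default steps of 0.05
#'   covering the observed range.
#' @return A tibble with one row per non-degenerate SD stratum; a degenerate
#'   all-zero-SD input yields a single flagged stratum.
#' @export
accuracy_by_variability <- function(report, breaks = NULL) {
  if (inherits(report, "cv_result")) report <- report$report
  stopifnot(inherits(report, "accuracy_report"))
  pp <- report$per_probe
  if (all(pp$target_sd == 0, na.rm = TRUE)) {
    return(tibble(sd_lo = 0, sd_hi = 0, n_probes = nrow(pp),
                  mean_r2 = NA_real_, mean_mae = mean(pp$mae, na.rm = TRUE),
                  frac_mae_below_sd = 0, degenerate = TRUE))
  }
  if (is.null(breaks)) {
    top <- max(pp$target_sd, na.rm = TRUE)
    breaks <- seq(0, ceiling(top / 0.05) * 0.05, by = 0.05)
  }
  pp$bin <- cut(pp$target_sd, breaks = breaks, include.lowest = TRUE,
                right = FALSE)
  pp |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      sd_lo = breaks[as.integer(.data$bin[1])],
      sd_hi = breaks[as.integer(.data$bin[1]) + 1],
      n_probes = dplyr::n(),
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      mean_mae = mean(.data$mae, na.rm = TRUE),
      frac_mae_below_sd = mean(.data$mae < .data$target_sd, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(degenerate = FALSE) |>
    dplyr::select(-"bin")
}

# bin index under the fixed convention: left-closed right-open bins on
# [0, 1), last bin closed at 1; a value exactly on an edge belongs to the
# bin whose left endpoint it is.
.bin_index <- function(v, n_bins) {
  pmin(floor(v * n_bins) + 1L, n_bins)
}

#' Bin-density diagnostic for one sample
#'
#' Categorizes probes into `n_bins` equally spaced bins of the measured
#' target value and asks, for the raw surrogate values and for each model's
#' predictions, what fraction falls inside the bin's interval. Calibrated
#' predictions should land inside the window of the measured target value
#' far more often than the uncalibrated surrogate values do.
#'
#' @param true_target Numeric vector: measured target betas for one sample.
#' @param surrogate Numeric vector: the raw surrogate betas.
#' @param lm_pred,svr_pred Optional prediction vectors from each engine.
#' @param n_bins Number of equal bins on \[0, 1\], default 10 (>= 2).
#' @return A tibble with one row per bin: bounds, probe count, and the
#'   within-bin fraction per value set, plus list-columns of the values.
#' @export
density_by_bin <- function(true_target, surrogate, lm_pred = NULL,
                           svr_pred = NULL, n_bins = 10) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  stopifnot(length(surrogate) == length(true_target))
  sets <- list(raw = surrogate)
  if (!is.null(lm_pred)) { stopifnot(length(lm_pred) == length(true_target)); sets$lm <- lm_pred }
  if (!is.null(svr_pred)) { stopifnot(length(svr_pred) == length(true_target)); sets$svr <- svr_pred }
  edges <- seq(0, 1, length.out = n_bins + 1)
  tb <- .bin_index(true_target, n_bins)
  purrr::map_dfr(seq_len(n_bins), function(b) {
    in_b <- !is.na(true_target) & tb == b
    row <- tibble(bin = b, lower = edges[b], upper = edges[b + 1],
                  n_probes = sum(in_b))
    for (nm in names(sets)) {
      vals <- sets[[nm]][in_b]
      vals <- vals[!is.na(vals)]
      frac <- if (length(vals) == 0) NA_real_ else
        mean(.bin_index(pmin(pmax(vals, 0), 1), n_bins) == b)
      row[[paste0("frac_", nm)]] <- frac
      row[[paste0("values_", nm)]] <- list(vals)
    }
    row
  })
}

.size_seed <- function(seed, size, replicate) {
  as.integer((as.numeric(seed) * 100003 + size * 1009 + replicate * 7) %%
               2147483647)
}

#' Training-sample-size experiment
#'
#' Quantifies how prediction accuracy depends on the size of the training
#' set: for each requested size, draws `replicates` random training subsets
#' (seeded; each cell of the grid is independently reproducible from
#' `(seed, size, replicate)`), fits both engines, predicts an independent
#' test set, and records the per test sample mean absolute difference across
#' probes plus per-probe mean absolute errors. The full-size entry uses all
#' training samples exactly once. Sizes below 3 are rejected: 3 paired
#' observations is the per-probe minimum for fitting.
#'
#' @param x_train,y_train Aligned training matrices (the pool subsets are
#'   drawn from).
#' @param x_test,y_test Aligned test matrices (never subsampled).
#' @param sizes Integer vector of training sizes; default
#'   `c(3, 4, 5, 6, 7, 8, 10, 20, 30, 39)` truncated to the available pool.
#' @param replicates Random subsets per size, default 10.
#' @param seed Base integer seed.
#' @param methods Engines to run, default both `"LM"` and `"SVR"`.
#' @param clamp Truncate predictions into \[0, 1\] before scoring.
#' @return A list of class `sample_size_result`: `grid` (size x replicate x
#'   method sample-level errors), `per_probe` (per-probe MAE averaged over
#'   replicates), `summary` (mean error per size and method).
#' @export
sample_size_experiment <- function(x_train, y_train, x_test, y_test,
                                   sizes = c(3, 4, 5, 6, 7, 8, 10, 20, 30, 39),
                                   replicates = 10, seed = 1,
                                   methods = c("LM", "SVR"), clamp = FALSE) {
  x_train <- validate_beta_matrix(x_train); y_train <- validate_beta_matrix(y_train)
  x_test <- validate_beta_matrix(x_test); y_test <- validate_beta_matrix(y_test)
  if (any(sizes < 3)) {
    abort("Training sizes below 3 are rejected: per-probe fitting needs >= 3 paired observations.")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  pool <- rownames(x_train)
  sizes <- sizes[sizes <= length(pool)]
  if (length(sizes) == 0) abort("No requested size fits the training pool.")
  xm_tr <- unclass(x_train); ym_tr <- unclass(y_train)
  grid <- list(); per_probe <- list()
  for (size in sizes) {
    reps <- if (size == length(pool)) 1L else replicates
    for (rep_i in seq_len(reps)) {
      subset_ids <- if (size == length(pool)) pool else
        withr::with_seed(.size_seed(seed, size, rep_i), sample(pool, size))
      x_sub <- beta_matrix(xm_tr[subset_ids, , drop = FALSE])
      y_sub <- beta_matrix(ym_tr[subset_ids, , drop = FALSE])
      for (method in methods) {
        fit <- fit_probe_models(x_sub, y_sub, method = method, quiet = TRUE)
        p <- predict_matrix(fit, x_test, clamp = clamp)
        abs_err <- abs(unclass(y_test) - p)
        grid[[length(grid) + 1]] <- tibble(
          size = size, replicate = rep_i, method = method,
          sample_id = rownames(abs_err),
          mean_abs_error = rowMeans(abs_err, na.rm = TRUE)
        )
        per_probe[[length(per_probe) + 1]] <- tibble(
          size = size, replicate = rep_i, method = method,
          probe_id = colnames(abs_err),
          mae = colMeans(abs_err, na.rm = TRUE),
          target_sd = apply(unclass(y_test), 2, sd, na.rm = TRUE)
        )
      }
    }
  }
  grid <- dplyr::bind_rows(grid)
  per_probe <- dplyr::bind_rows(per_probe) |>
    dplyr::group_by(.data$size, .data$method, .data$probe_id, .data$target_sd) |>
    dplyr::summarise(mae = mean(.data$mae, na.rm = TRUE), .groups = "drop")
  summary <- grid |>
    dplyr::group_by(.data$size, .data$method) |>
    dplyr::summarise(mean_abs_error = mean(.data$mean_abs_error, na.rm = TRUE),
                     n_replicates = dplyr::n_distinct(.data$replicate),
                     .groups = "drop")
  structure(list(grid = grid, per_probe = per_probe, summary = summary,
                 sizes = sizes, replicates = replicates, seed = seed),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("<sample_size_result>\n")
  print(tidyr::pivot_wider(x$summary, names_from = "method",
                           values_from = "mean_abs_error", id_cols = "size"))
  invisible(x)
}

#' @export
tidy.sample_size_result <- function(x, ...) x$summary

#' @export
glance.sample_size_result <- function(x, ...) {
  x$summary |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(error_at_min_n = .data$mean_abs_error[which.min(.data$size)],
                     error_at_max_n = .data$mean_abs_error[which.max(.data$size)],
                     .groups = "drop")
}
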