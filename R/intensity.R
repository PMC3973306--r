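#' Construct a probe intensity set
#'
#' Raw BeadChip measurements per sample x probe: methylated signal (M),
#' unmethylated signal (U), a detection p-value (probability that the signal
#' is indistinguishable from background) and, on 450k-style inputs, a bead
#' count. Beta values derive from these as `M / (M + U + offset)`.
#'
#' @param methylated,unmethylated Nonnegative numeric matrices
#'   (samples x probes) with matching dimnames.
#' @param detection_p Matrix of detection p-values in \[0, 1\], or `NULL`.
#' @param bead_count Matrix of nonnegative integer bead counts, or `NULL`
#'   (27k-style inputs have none).
#' @return A list of class `intensity_set`.
#' @export
intensity_set <- function(methylated, unmethylated, detection_p = NULL,
                          bead_count = NULL) {
  if (!identical(dim(methylated), dim(unmethylated))) {
    abort("Methylated and unmethylated matrices must share dimensions.")
  }
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE)) {
    abort("Signal intensities must be nonnegative.")
  }
  check_companion <- function(m, what, upper = NULL) {
    if (is.null(m)) return(NULL)
    if (!identical(dim(m), dim(methylated))) {
      abort(paste0(what, " matrix must share dimensions with the signals."))
    }
    if (!is.null(upper) && any(m < 0 | m > upper, na.rm = TRUE)) {
      abort(paste0(what, " values must lie in [0, ", upper, "]."))
    }
    if (is.null(upper) && any(m < 0, na.rm = TRUE)) {
      abort(paste0(what, " values must be nonnegative."))
    }
    dimnames(m) <- dimnames(methylated)
    m
  }
  detection_p <- check_companion(detection_p, "detection_p", upper = 1)
  bead_count <- check_companion(bead_count, "bead_count")
  structure(
    list(methylated = methylated, unmethylated = unmethylated,
         detection_p = detection_p, bead_count = bead_count),
    class = "intensity_set"
  )
}

#' @export
print.intensity_set <- function(x, ...) {
  cat(sprintf("<intensity_set> %d samples x %d probes (%s detection p, %s bead counts)\n",
              nrow(x$methylated), ncol(x$methylated),
              if (is.null(x$detection_p)) "no" else "with",
              if (is.null(x$bead_count)) "no" else "with"))
  invisible(x)
}

#' Compute beta values from probe intensities
#'
#' The methylation fraction is the ratio of methylated signal to total signal
#' plus a stabilizing offset: `beta = M / (M + U + offset)`. With a positive
#' offset the result is always strictly below 1; with `M = U = 0` it is 0.
#'
#' @param intensities An [intensity_set()].
#' @param offset Nonnegative stabilizing constant added to the denominator,
#'   default 100 (the BeadStudio convention).
#' @return A [beta_matrix()].
#' @export
compute_beta <- function(intensities, offset = 100) {
  stopifnot(inherits(intensities, "intensity_set"))
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0) {
    abort("`offset` must be a single nonnegative number.")
  }
  m <- intensities$methylated
  u <- intensities$unmethylated
  denom <- m + u + offset
  b <- m / denom
  b[denom == 0] <- 0  # only possible when offset = 0 and both signals are 0
  beta_matrix(b)
}
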