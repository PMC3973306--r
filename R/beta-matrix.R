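#' Construct a validated beta matrix
#'
#' A beta matrix holds methylation fractions (beta values) with samples in
#' rows and CpG probes in columns. Values must lie in \[0, 1\]; `NA` marks a
#' masked or missing measurement. Row and column names are the sample and
#' probe identifiers and must be unique.
#'
#' @param values Numeric matrix, samples x probes.
#' @param sample_ids Optional character vector of row identifiers; defaults
#'   to existing rownames.
#' @param probe_ids Optional character vector of column identifiers; defaults
#'   to existing colnames.
#' @return A numeric matrix of class `beta_matrix`.
#' @examples
#' b <- beta_matrix(matrix(c(0.1, 0.5, 0.9, 0.2), 2, 2),
#'                  sample_ids = c("s1", "s2"), probe_ids = c("cg1", "cg2"))
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        probe_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x probes).")
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample_%d", seq_len(nrow(values)))
  }
  if (is.null(probe_ids)) {
    probe_ids <- sprintf("probe_%d", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values) || length(probe_ids) != ncol(values)) {
    abort("Identifier lengths do not match matrix dimensions.")
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(probe_ids))
  out <- structure(values, class = c("beta_matrix", class(values)))
  validate_beta_matrix(out)
}

#' Validate a beta matrix
#'
#' Checks the invariants of the container: numeric matrix, unique sample and
#' probe identifiers, and all non-missing values in \[0, 1\]. Called by
#' [beta_matrix()] and by readers; exported so pipelines can re-assert
#' validity after manual manipulation.
#'
#' @param x Matrix to validate.
#' @return `x`, invisibly classed as `beta_matrix`.
#' @export
validate_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("A beta matrix must be a numeric matrix.")
  }
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    abort("A beta matrix must carry sample (row) and probe (column) names.")
  }
  if (is.null(rownames(x))) rownames(x) <- character(0)
  if (is.null(colnames(x))) colnames(x) <- character(0)
  if (anyDuplicated(rownames(x))) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    abort(paste0("Duplicate probe ids: ",
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(head(bad, 5), 1, function(ij) {
      sprintf("[%s, %s] = %g", rownames(x)[ij[1]], colnames(x)[ij[2]],
              x[ij[1], ij[2]])
    })
    abort(paste0("Beta values outside [0, 1] at ", nrow(bad), " cell(s): ",
                 paste(cells, collapse = "; "),
                 if (nrow(bad) > 5) " ..." else ""))
  }
  if (!inherits(x, "beta_matrix")) class(x) <- c("beta_matrix", class(x))
  invisible(x)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d samples x %d probes, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  mm <- unclass(x)
  print(mm[seq_len(min(5, nrow(mm))), seq_len(min(5, ncol(mm))), drop = FALSE])
  invisible(x)
}

#' Tidy a beta matrix into long format
#'
#' @param x A `beta_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `probe_id`, `beta`.
#' @export
tidy.beta_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    probe_id = rep(colnames(x), each = nrow(x)),
    beta = as.vector(unclass(x))
  )
}

#' Read a beta matrix from a delimited text file
#'
#' Expects tab-separated UTF-8 text with a header row; the first column holds
#' row identifiers and remaining columns are numeric beta values with `NA`
#' (configurable) marking missing cells. Fields containing the delimiter may
#' be quoted. The orientation flag states whether rows are samples
#' (the default) or probes; there is no auto-detection because a silently
#' transposed matrix is the most dangerous failure mode when n is much
#' smaller than m.
#'
#' @param path File path.
#' @param orientation `"samples-by-probes"` (default) or
#'   `"probes-by-samples"`; the returned matrix is always samples x probes.
#' @param na Missing-value token, default `"NA"`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples-by-probes",
                                             "probes-by-samples"),
                             na = "NA") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, na = na, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 1) abort(paste0("Malformed header in ", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate row ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  valcols <- df[-1]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(valcols),
              dimnames = list(ids, names(valcols)))
  for (j in seq_along(valcols)) {
    raw <- valcols[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric cell in %s at row '%s', column '%s': '%s'",
        path, ids[bad[1]], names(valcols)[j], raw[bad[1]]))
    }
    m[, j] <- num
  }
  if (orientation == "probes-by-samples") m <- t(m)
  beta_matrix(m)
}

#' Write a beta matrix to a tab-separated file
#'
#' Inverse of [read_beta_matrix()]: the written file round-trips exactly,
#' including missing cells and identifiers containing the delimiter (which
#' are quoted).
#'
#' @param m A `beta_matrix` (or validatable matrix).
#' @param path Output file path.
#' @param na Missing-value token, default `"NA"`.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(m, path, na = "NA") {
  m <- validate_beta_matrix(m)
  df <- tibble::as_tibble(unclass(m), rownames = "sample_id")
  readr::write_tsv(df, path, na = na, quote = "needed", escape = "double",
                   progress = FALSE)
  invisible(path)
}

#' Restrict two beta matrices to their common samples and probes
#'
#' Paired per-probe calibration requires the surrogate and target matrices to
#' share sample and probe identifiers in identical order. Both matrices are
#' restricted to the intersection of sample ids and probe ids (kept in the
#' order of `x`), and the number of dropped rows/columns is reported.
#'
#' @param x,y Beta matrices.
#' @param quiet Suppress the drop-count message.
#' @return A list with elements `x` and `y` (aligned `beta_matrix` objects)
#'   and `dropped`, a tibble of drop counts.
#' @export
align_matrices <- function(x, y, quiet = FALSE) {
  x <- validate_beta_matrix(x)
  y <- validate_beta_matrix(y)
  samples <- intersect(rownames(x), rownames(y))
  probes <- intersect(colnames(x), colnames(y))
  if (length(samples) == 0) abort("No samples in common between the matrices.")
  if (length(probes) == 0) abort("No probes in common between the matrices.")
  dropped <- tibble(
    matrix = c("x", "y"),
    samples_dropped = c(nrow(x) - length(samples), nrow(y) - length(samples)),
    probes_dropped = c(ncol(x) - length(probes), ncol(y) - length(probes))
  )
  if (!quiet && any(dropped$samples_dropped > 0 | dropped$probes_dropped > 0)) {
    inform(sprintf(
      "align_matrices: kept %d samples / %d probes (dropped %d+%d samples, %d+%d probes)",
      length(samples), length(probes),
      dropped$samples_dropped[1], dropped$samples_dropped[2],
      dropped$probes_dropped[1], dropped$probes_dropped[2]))
  }
  out_x <- beta_matrix(unclass(x)[samples, probes, drop = FALSE])
  out_y <- beta_matrix(unclass(y)[samples, probes, drop = FALSE])
  list(x = out_x, y = out_y, dropped = dropped)
}

#' Read a probe annotation table
#'
#' Tab-separated file with columns `probe_id`, `design_type` (`I`/`II`),
#' `category` (functional category such as island/shore/shelf/other) and
#' `snp_flag` (logical: probe overlaps a common SNP or has a SNP within
#' 10 bp).
#'
#' @param path File path.
#' @return A tibble with the four columns, validated.
#' @export
read_probe_annotation <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_probe_annotation(df)
}

#' Validate a probe annotation table
#'
#' @param ann Data frame with columns `probe_id`, `design_type`, `category`,
#'   `snp_flag`.
#' @return The annotation as a tibble, invisibly valid.
#' @export
validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "design_type", "category", "snp_flag")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("Probe annotation lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ann <- as_tibble(ann)
  ann$probe_id <- as.character(ann$probe_id)
  ann$design_type <- as.character(ann$design_type)
  ann$category <- as.character(ann$category)
  ann$snp_flag <- as.logical(ann$snp_flag)
  if (anyDuplicated(ann$probe_id)) abort("Duplicate probe ids in annotation.")
  if (!all(ann$design_type %in% c("I", "II"))) {
    abort("`design_type` must be 'I' or 'II'.")
  }
  if (any(is.na(ann$category) | ann$category == "")) {
    abort("`category` must be non-empty for every probe.")
  }
  ann
}

#' Validate sample metadata
#'
#' Sample metadata carries one record per sample: `sample_id`, a `family_id`
#' grouping label used by leave-one-family-out cross-validation, and an
#' optional binary `outcome` (0/1 case-control status).
#'
#' @param meta Data frame with at least `sample_id` and `family_id`.
#' @param beta Optional beta matrix; if given, every sample in `beta` must
#'   have exactly one metadata record.
#' @return The metadata as a tibble.
#' @export
validate_sample_metadata <- function(meta, beta = NULL) {
  need <- c("sample_id", "family_id")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  meta <- as_tibble(meta)
  meta$sample_id <- as.character(meta$sample_id)
  meta$family_id <- as.character(meta$family_id)
  if (anyDuplicated(meta$sample_id)) abort("Duplicate sample ids in metadata.")
  if ("outcome" %in% names(meta)) {
    ok <- is.na(meta$outcome) | meta$outcome %in% c(0, 1)
    if (!all(ok)) abort("`outcome` must be binary (0/1) or NA.")
  }
  if (!is.null(beta)) {
    beta <- validate_beta_matrix(beta)
    absent <- setdiff(rownames(beta), meta$sample_id)
    if (length(absent) > 0) {
      abort(paste0("Samples without metadata: ", paste(absent, collapse = ", ")))
    }
  }
  meta
}
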