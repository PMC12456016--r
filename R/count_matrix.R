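#' Construct a two-group microbiome count matrix
#'
#' The basic data container used throughout the package: an integer matrix of
#' taxa (rows) by samples (columns) together with a two-level group factor
#' over the samples. Group labels default to the conventional "S1"/"S2".
#'
#' @param counts Non-negative integer matrix, taxa in rows, samples in
#'   columns.
#' @param taxon_ids Character vector of unique row identifiers. Defaults to
#'   existing rownames, or `taxon_1 ... taxon_T`.
#' @param sample_ids Character vector of unique column identifiers. Defaults
#'   to existing colnames, or `sample_1 ... sample_S`.
#' @param groups Factor (or coercible) of length `ncol(counts)` with exactly
#'   two levels assigning each sample to an experimental group.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames) and `groups` (named factor).
#' @export
count_matrix <- function(counts, taxon_ids = NULL, sample_ids = NULL, groups) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("`counts` must be a numeric matrix")
  }
  if (any(!is.finite(counts))) {
    stop("`counts` contains non-finite values")
  }
  if (any(counts < 0)) {
    stop("`counts` contains negative values")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be integer-valued")
  }
  # integer storage where it fits; counts beyond the 32-bit range (extreme
  # group-effect draws) stay as integer-valued doubles
  if (max(counts) <= .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  } else {
    counts <- round(counts)
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- rownames(counts)
    if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(nrow(counts)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(counts)))
  }
  if (length(taxon_ids) != nrow(counts)) {
    stop("length of `taxon_ids` does not match number of rows")
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length of `sample_ids` does not match number of columns")
  }
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("`groups` must have one entry per sample")
  }
  if (nlevels(droplevels(groups)) != 2) {
    stop("`groups` must have exactly two levels")
  }
  groups <- droplevels(groups)
  dimnames(counts) <- list(taxon_ids, sample_ids)
  names(groups) <- sample_ids
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d taxa x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s: n=%d", levels(x$groups), tabulate(x$groups)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Split sample indices by group
#'
#' @param m A `count_matrix`.
#' @return Named list of two integer vectors of column indices, one per group
#'   level.
#' @keywords internal
group_indices <- function(m) {
  split(seq_along(m$groups), m$groups)
}

stopifnot_count_matrix <- function(m) {
  if (!inherits(m, "count_matrix")) stop("expected a `count_matrix` object")
  invisible(m)
}
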