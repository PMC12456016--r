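#' Contaminant injection parameters
#'
#' Contaminant taxa are appended to a count matrix with counts drawn from a
#' Normal distribution clipped to `[0, max_count]` and rounded, so a
#' substantial fraction of cells come out zero (the sub-zero tail of the
#' Normal). Two manifestations are modelled: `"unweighted"` contamination
#' draws identically for every sample (the group-balanced scenario of
#' comparable starting biomass between groups), while `"weighted"`
#' contamination multiplies the pre-clipping mean for group S1 by
#' `bias_ratio` (the group-biased scenario of disparate starting biomass,
#' e.g. infection case vs control).
#'
#' The pre-clipping draw distribution is Normal(mean `max_count / 2`, sd
#' `max_count / 2`); `max_count = "level"` ties the range of the generator to
#' the number of contaminants injected (`N = C`) instead of a fixed ceiling.
#'
#' @param mode `"unweighted"` or `"weighted"`.
#' @param n_contaminants Number of contaminant taxa to inject (>= 0).
#' @param max_count Positive ceiling `N` of the clipped count range, or the
#'   string `"level"` for `N = n_contaminants`.
#' @param bias_ratio Ratio (>= 1) of group S1's pre-clipping mean to group
#'   S2's; used only in weighted mode. `bias_ratio = 1` reduces the weighted
#'   draw to the unweighted one.
#' @param seed Integer seed for the injection draws.
#' @return A list of class `contamination_spec`.
#' @export
contamination_spec <- function(mode = c("unweighted", "weighted"),
                               n_contaminants, max_count = 100,
                               bias_ratio = 3, seed = 1L) {
  mode <- match.arg(mode)
  n_contaminants <- as.integer(n_contaminants)
  if (is.na(n_contaminants) || n_contaminants < 0) {
    stop("`n_contaminants` must be >= 0")
  }
  if (identical(max_count, "level")) {
    max_count <- max(n_contaminants, 1L)
  }
  if (!is.numeric(max_count) || !is.finite(max_count) || max_count < 1) {
    stop("`max_count` must be >= 1 or \"level\"")
  }
  if (!is.finite(bias_ratio) || bias_ratio < 1) {
    stop("`bias_ratio` must be >= 1")
  }
  structure(list(mode = mode, n_contaminants = n_contaminants,
                 max_count = max_count, bias_ratio = bias_ratio,
                 seed = as.integer(seed)),
            class = "contamination_spec")
}

#' Inject simulated contaminant taxa into a count matrix
#'
#' Appends `n_contaminants` rows with identifiers prefixed `CONTAM_`
#' (guaranteed disjoint from simulated taxon identifiers) whose counts are
#' independent clipped-and-rounded Normal draws as described in
#' [contamination_spec()]. Removing the flagged rows recovers the input
#' matrix exactly.
#'
#' @param m A [count_matrix()].
#' @param spec A [contamination_spec()].
#' @return A list of class `contaminated_matrix` with elements `matrix` (the
#'   augmented `count_matrix`) and `contaminant_ids` (character vector of
#'   injected row identifiers, empty when `n_contaminants = 0`).
#' @export
inject_contaminants <- function(m, spec) {
  stopifnot_count_matrix(m)
  if (!inherits(spec, "contamination_spec")) {
    stop("expected a `contamination_spec`")
  }
  if (spec$mode == "weighted") inject_weighted(m, spec) else inject_unweighted(m, spec)
}

#' @rdname inject_contaminants
#' @export
inject_unweighted <- function(m, spec) {
  stopifnot_count_matrix(m)
  if (spec$mode != "unweighted") stop("spec mode must be \"unweighted\"")
  inject_impl(m, spec, mean_by_group = rep(spec$max_count / 2, 2L))
}

#' @rdname inject_contaminants
#' @export
inject_weighted <- function(m, spec) {
  stopifnot_count_matrix(m)
  if (spec$mode != "weighted") stop("spec mode must be \"weighted\"")
  if (spec$bias_ratio < 1) stop("`bias_ratio` must be >= 1")
  base_mean <- spec$max_count / 2
  # group S1 (first level) receives bias_ratio x the mean of group S2
  inject_impl(m, spec, mean_by_group = c(spec$bias_ratio * base_mean, base_mean))
}

inject_impl <- function(m, spec, mean_by_group) {
  n_c <- spec$n_contaminants
  if (n_c == 0L) {
    return(structure(list(matrix = m, contaminant_ids = character(0)),
                     class = "contaminated_matrix"))
  }
  n_s <- ncol(m$counts)
  sdev <- spec$max_count / 2
  mu <- mean_by_group[as.integer(m$groups)] # per sample
  set.seed(spec$seed)
  raw <- matrix(stats::rnorm(n_c * n_s, mean = rep(mu, each = n_c), sd = sdev),
                nrow = n_c)
  counts <- round(pmin(pmax(raw, 0), spec$max_count))
  ids <- sprintf("CONTAM_%03d", seq_len(n_c))
  if (any(ids %in% rownames(m$counts))) {
    stop("input matrix already contains CONTAM_-prefixed taxa")
  }
  aug <- count_matrix(rbind(m$counts, counts),
                      taxon_ids = c(rownames(m$counts), ids),
                      sample_ids = colnames(m$counts),
                      groups = m$groups)
  structure(list(matrix = aug, contaminant_ids = ids),
            class = "contaminated_matrix")
}

#' Remove flagged contaminant rows
#'
#' @param cm A `contaminated_matrix`.
#' @return The original `count_matrix` with injected rows removed.
#' @export
strip_contaminants <- function(cm) {
  if (!inherits(cm, "contaminated_matrix")) stop("expected a `contaminated_matrix`")
  m <- cm$matrix
  keep <- !(rownames(m$counts) %in% cm$contaminant_ids)
  count_matrix(m$counts[keep, , drop = FALSE],
               taxon_ids = rownames(m$counts)[keep],
               sample_ids = colnames(m$counts),
               groups = m$groups)
}
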