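#' Load genus-level contaminant lists
#'
#' Published "kitome" lists name genera found as contaminants in laboratory
#' reagents. Two input dialects are accepted: a set of plain-text files (one
#' genus per line, one list per file, named after the file) or a single
#' two-column CSV with columns `list_name` and `genus`. Genus names are
#' normalised: whitespace-trimmed, bracketed qualifiers (e.g.
#' `[Clostridium]`) stripped, case-folded to a capitalised form. Synonymy is
#' not resolved. Duplicates within a list are dropped.
#'
#' @param paths Character vector of one or more plain-text list files, or a
#'   single CSV path.
#' @return A named list of character vectors of class `genus_list_set`.
#' @export
read_genus_lists <- function(paths) {
  if (length(paths) == 1 && grepl("\\.csv$", paths, ignore.case = TRUE)) {
    tab <- utils::read.csv(paths, stringsAsFactors = FALSE)
    if (!all(c("list_name", "genus") %in% names(tab))) {
      stop("CSV dialect needs columns `list_name` and `genus`")
    }
    lists <- split(tab$genus, tab$list_name)
  } else {
    lists <- lapply(paths, readLines)
    names(lists) <- sub("\\.[^.]*$", "", basename(paths))
  }
  genus_list_set(lists)
}

#' @rdname read_genus_lists
#' @param lists Named list of character vectors of genus names.
#' @export
genus_list_set <- function(lists) {
  if (length(lists) == 0) stop("empty list set")
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- paste0("list_", seq_along(lists))
  }
  lists <- lapply(lists, function(x) {
    x <- normalise_genus(x)
    x <- x[nzchar(x)]
    unique(x)
  })
  if (any(lengths(lists) == 0)) stop("a list contains no valid genus names")
  structure(lists, class = "genus_list_set")
}

normalise_genus <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("\\[|\\]|\\(.*\\)", "", x)
  x <- trimws(x)
  low <- tolower(x)
  out <- paste0(toupper(substring(low, 1, 1)), substring(low, 2))
  out[!nzchar(x)] <- ""
  out
}

#' Concordance statistics for genus contaminant lists
#'
#' Exact set algebra across the lists: the size of the union, the number of
#' lists naming each genus, the histogram of those counts (how many genera
#' appear in exactly 1, 2, ... lists), and the number of genera appearing in
#' a strict majority (> 50%) of the lists.
#'
#' @param lists A `genus_list_set`.
#' @return List of class `overlap_stats`: `n_lists`, `union_size`,
#'   `per_genus_counts` (named integer vector), `histogram` (named vector
#'   indexed by number of lists), `n_majority`.
#' @export
overlap_stats <- function(lists) {
  if (!inherits(lists, "genus_list_set")) lists <- genus_list_set(lists)
  all_genera <- unlist(lists, use.names = FALSE)
  counts <- table(all_genera)
  per_genus <- as.integer(counts)
  names(per_genus) <- names(counts)
  hist <- tabulate(per_genus, nbins = length(lists))
  names(hist) <- seq_along(hist)
  structure(list(
    n_lists = length(lists),
    union_size = length(per_genus),
    per_genus_counts = per_genus,
    histogram = hist,
    n_majority = sum(per_genus > length(lists) / 2)
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "%d lists, %d genera in the union; %d singletons; %d in >50%% of lists\n",
    x$n_lists, x$union_size, unname(x$histogram["1"]), x$n_majority))
  invisible(x)
}

#' Filter a count matrix by genus contaminant lists
#'
#' Removes taxa whose genus appears in at least `k` of the supplied lists.
#' A caveat applies: such list-based filtering can be very aggressive,
#' removing genuine residents of low-biomass environments; the function
#' exists to let users quantify that aggressiveness.
#'
#' @param m A [count_matrix()].
#' @param lists A `genus_list_set`.
#' @param genus_map Named character vector mapping `taxon_id` to genus; if
#'   `NULL`, taxon identifiers are taken to be genus names already.
#' @param k Minimum number of lists a genus must appear in to be removed
#'   (default 1).
#' @return The filtered `count_matrix`, with attribute `n_removed`. Removing
#'   every taxon is an error-free but warned-about edge case yielding a
#'   zero-row matrix.
#' @export
filter_by_lists <- function(m, lists, genus_map = NULL, k = 1L) {
  stopifnot_count_matrix(m)
  if (!inherits(lists, "genus_list_set")) lists <- genus_list_set(lists)
  ids <- rownames(m$counts)
  if (is.null(genus_map)) {
    genera <- ids
  } else {
    genera <- unname(genus_map[ids])
    if (any(is.na(genera))) stop("`genus_map` is missing some taxon_ids")
  }
  genera <- normalise_genus(genera)
  counts <- overlap_stats(lists)$per_genus_counts
  hits <- counts[genera]
  hits[is.na(hits)] <- 0L
  remove <- hits >= k
  if (all(remove)) warning("filter removes every taxon in the matrix")
  keep_counts <- m$counts[!remove, , drop = FALSE]
  out <- structure(list(counts = keep_counts, groups = m$groups),
                   class = "count_matrix")
  attr(out, "n_removed") <- sum(remove)
  out
}
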