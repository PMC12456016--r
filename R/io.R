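#' Write / read a count matrix as TSV
#'
#' The matrix file is tab-separated with taxa as rows: first column
#' `taxon_id`, remaining columns one per sample. The companion metadata file
#' has columns `sample_id` and `group`. `write_count_matrix()` followed by
#' `read_count_matrix()` is a lossless round trip.
#'
#' @param m A [count_matrix()].
#' @param path Path of the matrix TSV.
#' @param metadata_path Path of the metadata TSV; defaults to `path` with a
#'   `_metadata.tsv` suffix.
#' @return `write_count_matrix()`: the paths, invisibly.
#'   `read_count_matrix()`: a `count_matrix`.
#' @export
write_count_matrix <- function(m, path,
                               metadata_path = default_metadata_path(path)) {
  stopifnot_count_matrix(m)
  tab <- data.frame(taxon_id = rownames(m$counts), m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(m$counts),
                     group = as.character(m$groups),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = path, metadata = metadata_path))
}

default_metadata_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0("_metadata.tsv")
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path,
                              metadata_path = default_metadata_path(path)) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "taxon_id") {
    stop("format error: first column must be `taxon_id`")
  }
  taxa <- tab$taxon_id
  if (anyDuplicated(taxa)) stop("format error: duplicate taxon_id values")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("format error: non-numeric counts")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("format error: invalid count at taxon `%s`, sample `%s`",
                 taxa[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    stop("format error: metadata needs `sample_id` and `group` columns")
  }
  if (!setequal(meta$sample_id, colnames(counts)) ||
      anyDuplicated(meta$sample_id)) {
    stop("format error: metadata samples do not match matrix columns")
  }
  groups <- meta$group[match(colnames(counts), meta$sample_id)]
  count_matrix(counts, taxon_ids = taxa, sample_ids = colnames(counts),
               groups = groups)
}

#' Simulate a grid of datasets to disk
#'
#' Writes one count-matrix TSV (plus metadata TSV) per design cell, a
#' one-column `*_contaminants.txt` file for contaminated cells, and a
#' `manifest.csv` indexing every file by the cell's coordinates.
#'
#' @param cells List of `design_cell`s from [make_grid()].
#' @param dir Output directory (created if missing).
#' @param model_args Named list passed on to [default_model()].
#' @param contam_args Named list passed on to [contamination_spec()]
#'   (`max_count`, `bias_ratio`).
#' @return The manifest data frame, invisibly.
#' @export
simulate_grid_to_dir <- function(cells, dir, model_args = list(),
                                 contam_args = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    model <- do.call(default_model, c(list(cell), model_args))
    m <- simulate_counts(cell, model)
    contam_ids <- character(0)
    if (cell$contam_level > 0) {
      spec <- do.call(contamination_spec,
                      c(list(mode = cell$contam_mode,
                             n_contaminants = cell$contam_level,
                             seed = child_seed(cell$seed, "contam")),
                        contam_args))
      cm <- inject_contaminants(m, spec)
      m <- cm$matrix
      contam_ids <- cm$contaminant_ids
    }
    stem <- sprintf("cell_%03d", i)
    write_count_matrix(m, file.path(dir, paste0(stem, ".tsv")))
    if (length(contam_ids)) {
      writeLines(contam_ids, file.path(dir, paste0(stem, "_contaminants.txt")))
    }
    manifest[[i]] <- data.frame(
      cell = i, file = paste0(stem, ".tsv"),
      n_per_group = cell$n_per_group, n_taxa = cell$n_taxa,
      sigma2 = cell$sigma2, contam_level = cell$contam_level,
      contam_mode = cell$contam_mode, seed = cell$seed,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write all tidy result tables of an experiment
#'
#' Writes `outcomes.csv`, `fp_breakdown.csv`, `thresholds.csv`, `anova.csv`
#' and the echoed configuration (`config.yaml`) to a directory, so a results
#' directory is self-describing.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_experiment <- function(result, dir) {
  if (!inherits(result, "experiment_result")) stop("expected an `experiment_result`")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$outcomes, "outcomes.csv")
  if (!is.null(result$fp)) {
    wr(result$fp, "fp_breakdown.csv")
    long <- fp_long(result$fp)
    wr(fp_anova(long), "anova.csv")
  }
  if (any(result$outcomes$contam_level > 0)) {
    wr(threshold_table(result$outcomes), "thresholds.csv")
  }
  cfg <- result$config
  class(cfg) <- NULL
  cfg$drop_cells <- if (is.null(cfg$drop_cells)) NULL else cfg$drop_cells
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  writeLines(experiment_data_dictionary(), file.path(dir, "data_dictionary.txt"))
  paths <- c(paths, file.path(dir, "config.yaml"),
             file.path(dir, "data_dictionary.txt"))
  invisible(paths)
}

experiment_data_dictionary <- function() {
  c("Column dictionary for experiment result tables",
    "",
    "outcomes.csv (one row per design cell x replicate x contamination combination):",
    "  n_per_group, n_taxa, sigma2   design-cell coordinates",
    "  replicate                     replicate seed index",
    "  contam_mode, contam_level     contamination scenario (none/0 = clean)",
    "  margalef_p, simpson_p         paired t-test p-values, alpha diversity",
    "  bray_p, bray_F                PERMANOVA p and pseudo-F, Bray-Curtis",
    "  binomial_p, binomial_F        PERMANOVA p and pseudo-F, binomial deviance",
    "  nsig_nb_wald                  taxa significant at q <= alpha, NB Wald test",
    "  nsig_bias_corrected           same, compositional bias-corrected test",
    "  fc_<metric>_p                 p-value fold change vs the matched clean run",
    "  delta_nsig_<method>           signed change in significant-taxon count vs clean",
    "",
    "fp_breakdown.csv (one row per contaminated combination x DA method):",
    "  n_contaminant                 significant injected contaminants",
    "  n_borderline                  newly significant taxa, clean q in (0.05, 0.1]",
    "  n_random                      newly significant taxa, clean q > 0.1",
    "  n_false_positive              sum of the three categories",
    "  n_significant                 all significant taxa in the contaminated run",
    "  fp_proportion                 n_false_positive / n_significant (0 if none)",
    "",
    "thresholds.csv (one row per contamination mode x response):",
    "  response                      fold-change or |delta significant| series",
    "  criterion                     fold_change_2 or delta_sig_2",
    "  slope, intercept              OLS fit of response on contaminant level",
    "  n_star                        level solving the fitted line = 2 (NA: slope <= 0)",
    "  n_points                      observations in the fit",
    "",
    "anova.csv: two-way ANOVA of false-positive proportion ~ method * category.")
}
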