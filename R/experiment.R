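#' Configuration for a full simulation experiment
#'
#' Bundles the grid axes, community-model parameters, contamination
#' parameters, analysis toggles and the master seed for [run_experiment()].
#' Defaults reproduce the package's full study conditions: the 5 x 5 x 5
#' community grid crossed with contaminant levels {0, 1, 5, 10, 100} in both
#' contamination modes.
#'
#' @param n_per_group,n_taxa,sigma2 Community grid axes (see [make_grid()]).
#' @param contam_levels Contaminant levels; 0 denotes the clean dataset.
#' @param contam_modes Contamination modes among `"unweighted"`,
#'   `"weighted"`.
#' @param n_replicates Replicate datasets per design cell (independent
#'   seeds).
#' @param master_seed Master seed; every stage seed is derived from it.
#' @param intercept_mean,intercept_sd,dispersion Community-model parameters
#'   (see [default_model()]).
#' @param max_count,bias_ratio Contaminant-generator parameters (see
#'   [contamination_spec()]).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param alpha Significance threshold on adjusted q-values (default 0.05).
#' @param do_diversity,do_da Analysis toggles.
#' @param drop_cells Optional base-cell indices to exclude (see
#'   [make_grid()]).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_per_group = c(10, 30, 60, 120, 240),
                              n_taxa = c(10, 100, 1000, 2000, 5000),
                              sigma2 = c(0.1, 1, 10, 50, 100),
                              contam_levels = c(0, 1, 5, 10, 100),
                              contam_modes = c("unweighted", "weighted"),
                              n_replicates = 1L,
                              master_seed = 1L,
                              intercept_mean = 2, intercept_sd = 2,
                              dispersion = 0.5,
                              max_count = 100, bias_ratio = 3,
                              n_permutations = 999L,
                              alpha = 0.05,
                              do_diversity = TRUE, do_da = TRUE,
                              drop_cells = NULL) {
  contam_modes <- match.arg(contam_modes, several.ok = TRUE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  structure(
    list(n_per_group = n_per_group, n_taxa = n_taxa, sigma2 = sigma2,
         contam_levels = as.integer(contam_levels),
         contam_modes = contam_modes,
         n_replicates = as.integer(n_replicates),
         master_seed = as.integer(master_seed),
         intercept_mean = intercept_mean, intercept_sd = intercept_sd,
         dispersion = dispersion,
         max_count = max_count, bias_ratio = bias_ratio,
         n_permutations = as.integer(n_permutations),
         alpha = alpha,
         do_diversity = do_diversity, do_da = do_da,
         drop_cells = drop_cells),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [experiment_config()], organised
#' as `grid:` (`n_per_group`, `n_taxa`, `sigma2`, `contam_levels`,
#' `contam_modes`), `model:` (`intercept_mean`, `intercept_sd`,
#' `dispersion`), `contamination:` (`max_count`, `bias_ratio`), and
#' top-level `n_replicates`, `master_seed`, `n_permutations`, `alpha`.
#' Unknown keys are a configuration error.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("grid", "model", "contamination", "n_replicates",
                 "master_seed", "n_permutations", "alpha",
                 "do_diversity", "do_da", "drop_cells")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  args <- list()
  grab <- function(block, keys) {
    for (k in keys) {
      if (is.null(block[[k]])) next
      v <- unlist(block[[k]], use.names = FALSE) # YAML mixed int/float -> list
      args[[k]] <<- v
    }
  }
  grab(raw$grid, c("n_per_group", "n_taxa", "sigma2", "contam_levels", "contam_modes"))
  grab(raw$model, c("intercept_mean", "intercept_sd", "dispersion"))
  grab(raw$contamination, c("max_count", "bias_ratio"))
  grab(raw, setdiff(known_top, c("grid", "model", "contamination")))
  do.call(experiment_config, args)
}

#' Run all statistical analyses on one count matrix
#'
#' @param m A [count_matrix()].
#' @param config An `experiment_config` (supplies toggles, alpha,
#'   permutations).
#' @param seed Integer seed for the permutation tests.
#' @return A list: `margalef_p`, `simpson_p`, `bray_p`, `bray_F`,
#'   `binomial_p`, `binomial_F` (NA when diversity is toggled off), and
#'   `da` (named list of `da_result` per method, NULL when toggled off).
#' @export
analyse_matrix <- function(m, config = experiment_config(), seed = 1L) {
  out <- list(margalef_p = NA_real_, simpson_p = NA_real_,
              bray_p = NA_real_, bray_F = NA_real_,
              binomial_p = NA_real_, binomial_F = NA_real_,
              da = NULL)
  if (config$do_diversity) {
    out$margalef_p <- alpha_diversity(m, "margalef")$p_value
    out$simpson_p <- alpha_diversity(m, "simpson")$p_value
    pb <- permanova(bray_curtis(m), m$groups,
                    n_permutations = config$n_permutations,
                    seed = child_seed(seed, "perm", "bray"))
    out$bray_p <- pb$p_value
    out$bray_F <- pb$pseudo_F
    pn <- permanova(binomial_dissimilarity(m), m$groups,
                    n_permutations = config$n_permutations,
                    seed = child_seed(seed, "perm", "binomial"))
    out$binomial_p <- pn$p_value
    out$binomial_F <- pn$pseudo_F
  }
  if (config$do_da) {
    out$da <- list(nb_wald = nb_wald_test(m, alpha = config$alpha),
                   bias_corrected = bias_corrected_test(m, alpha = config$alpha))
  }
  out
}

#' Run the full simulation experiment
#'
#' For every community design cell and replicate: simulate the clean
#' dataset, analyse it, then inject contaminants at every requested
#' (mode, level) combination, re-analyse, and record p-value fold changes,
#' changes in the number of significant taxa, and the false-positive
#' breakdown against the clean analysis. Fully reproducible given the
#' master seed; a rerun with the same configuration yields byte-identical
#' tables. Cells whose clean analysis fails (e.g. a degenerate all-zero
#' sample) are recorded with NA outcomes and a message.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-cell progress.
#' @return A list of class `experiment_result`: `outcomes` (one row per
#'   cell x replicate x contamination combination, clean rows have
#'   `contam_mode = "none"`), `fp` (false-positive breakdown, one row per
#'   contaminated combination x DA method), and `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  if (!inherits(config, "experiment_config")) stop("expected an `experiment_config`")
  base <- expand.grid(sigma2 = config$sigma2, n_taxa = config$n_taxa,
                      n_per_group = config$n_per_group,
                      KEEP.OUT.ATTRS = FALSE)[, c("n_per_group", "n_taxa", "sigma2")]
  if (!is.null(config$drop_cells)) base <- base[-config$drop_cells, , drop = FALSE]
  levels_pos <- sort(unique(config$contam_levels[config$contam_levels > 0]))

  outcome_rows <- list()
  fp_rows <- list()
  for (i in seq_len(nrow(base))) {
    for (r in seq_len(config$n_replicates)) {
      cell_seed <- child_seed(config$master_seed, i, r)
      cell <- design_cell(base$n_per_group[i], base$n_taxa[i], base$sigma2[i],
                          seed = cell_seed)
      model <- default_model(cell, config$intercept_mean, config$intercept_sd,
                             config$dispersion)
      m_clean <- simulate_counts(cell, model)
      key <- data.frame(n_per_group = cell$n_per_group, n_taxa = cell$n_taxa,
                        sigma2 = cell$sigma2, replicate = r,
                        stringsAsFactors = FALSE)
      clean <- tryCatch(
        analyse_matrix(m_clean, config, seed = child_seed(cell_seed, "clean")),
        error = function(e) e
      )
      if (inherits(clean, "error")) {
        warning(sprintf("clean analysis failed for cell %d replicate %d: %s",
                        i, r, conditionMessage(clean)))
        outcome_rows[[length(outcome_rows) + 1L]] <-
          cbind(key, outcome_fields(NULL, NULL, level = 0L, mode = "none"))
        next
      }
      outcome_rows[[length(outcome_rows) + 1L]] <-
        cbind(key, outcome_fields(clean, clean, level = 0L, mode = "none"))
      if (verbose) {
        message(sprintf("cell %d/%d rep %d: n=%d taxa=%d sigma2=%g",
                        i, nrow(base), r, cell$n_per_group, cell$n_taxa,
                        cell$sigma2))
      }

      if (length(levels_pos) == 0 ||
          length(config$contam_modes) == 0) next
      for (mode in config$contam_modes) {
        for (lev in levels_pos) {
          spec <- contamination_spec(
            mode = mode, n_contaminants = lev,
            max_count = config$max_count, bias_ratio = config$bias_ratio,
            seed = child_seed(cell_seed, "contam", mode, lev)
          )
          cm <- inject_contaminants(m_clean, spec)
          cont <- tryCatch(
            analyse_matrix(cm$matrix, config,
                           seed = child_seed(cell_seed, "cont", mode, lev)),
            error = function(e) e
          )
          if (inherits(cont, "error")) {
            warning(sprintf(
              "contaminated analysis failed (cell %d rep %d %s level %d): %s",
              i, r, mode, lev, conditionMessage(cont)))
            next
          }
          outcome_rows[[length(outcome_rows) + 1L]] <-
            cbind(key, outcome_fields(cont, clean, level = lev, mode = mode))
          if (!is.null(cont$da)) {
            for (method in names(cont$da)) {
              fb <- classify_false_positives(clean$da[[method]],
                                             cont$da[[method]],
                                             cm$contaminant_ids)
              fp_rows[[length(fp_rows) + 1L]] <- cbind(
                key,
                data.frame(contam_mode = mode, contam_level = lev,
                           method = method,
                           n_contaminant = unname(fb$counts["contaminant"]),
                           n_borderline = unname(fb$counts["borderline"]),
                           n_random = unname(fb$counts["random"]),
                           n_false_positive = fb$n_false_positive,
                           n_significant = fb$n_significant,
                           fp_proportion = fb$fp_proportion,
                           stringsAsFactors = FALSE)
              )
            }
          }
        }
      }
    }
  }
  structure(list(outcomes = do.call(rbind, outcome_rows),
                 fp = if (length(fp_rows)) do.call(rbind, fp_rows) else NULL,
                 config = config),
            class = "experiment_result")
}

# one outcome row: absolute outcomes plus fold changes / deltas vs clean
outcome_fields <- function(res, clean, level, mode) {
  na_row <- function() {
    data.frame(contam_mode = mode, contam_level = level,
               margalef_p = NA_real_, simpson_p = NA_real_,
               bray_p = NA_real_, bray_F = NA_real_,
               binomial_p = NA_real_, binomial_F = NA_real_,
               nsig_nb_wald = NA_integer_, nsig_bias_corrected = NA_integer_,
               fc_margalef_p = NA_real_, fc_simpson_p = NA_real_,
               fc_bray_p = NA_real_, fc_binomial_p = NA_real_,
               delta_nsig_nb_wald = NA_integer_,
               delta_nsig_bias_corrected = NA_integer_,
               stringsAsFactors = FALSE)
  }
  if (is.null(res)) return(na_row())
  fc <- function(p_cont, p_clean) {
    if (!is.finite(p_cont) || !is.finite(p_clean) || p_clean <= 0) return(NA_real_)
    p_fold_change(p_cont, p_clean)
  }
  nsig <- function(x, method) {
    if (is.null(x$da)) NA_integer_ else n_significant(x$da[[method]])
  }
  data.frame(
    contam_mode = mode, contam_level = level,
    margalef_p = res$margalef_p, simpson_p = res$simpson_p,
    bray_p = res$bray_p, bray_F = res$bray_F,
    binomial_p = res$binomial_p, binomial_F = res$binomial_F,
    nsig_nb_wald = nsig(res, "nb_wald"),
    nsig_bias_corrected = nsig(res, "bias_corrected"),
    fc_margalef_p = fc(res$margalef_p, clean$margalef_p),
    fc_simpson_p = fc(res$simpson_p, clean$simpson_p),
    fc_bray_p = fc(res$bray_p, clean$bray_p),
    fc_binomial_p = fc(res$binomial_p, clean$binomial_p),
    delta_nsig_nb_wald = nsig(res, "nb_wald") - nsig(clean, "nb_wald"),
    delta_nsig_bias_corrected =
      nsig(res, "bias_corrected") - nsig(clean, "bias_corrected"),
    stringsAsFactors = FALSE
  )
}

#' Contaminant-threshold estimates from experiment outcomes
#'
#' Pools the contaminated rows of an outcome table by contamination mode and
#' fits [threshold_for_criterion()] for each response: fold change in each
#' diversity p-value (criterion: twofold change) and absolute change in each
#' method's number of significant taxa (criterion: change of two). Rows
#' whose clean p-value underflowed the double-precision minimum are excluded
#' from fold-change fits (the ratio is numerically meaningless there);
#' underflow cannot occur for the permutation-based beta-diversity p-values,
#' which are bounded below by 1/(n_permutations + 1).
#'
#' @param outcomes The `outcomes` table of an [run_experiment()] result.
#' @return Data frame with one row per (mode, response): `contam_mode`,
#'   `response`, `criterion`, `slope`, `intercept`, `n_star`, `n_points`.
#' @export
threshold_table <- function(outcomes) {
  clean <- outcomes[outcomes$contam_level == 0, , drop = FALSE]
  cont <- outcomes[outcomes$contam_level > 0, , drop = FALSE]
  if (nrow(cont) == 0) stop("no contaminated rows in outcomes")
  keycols <- c("n_per_group", "n_taxa", "sigma2", "replicate")
  merged <- merge(cont, clean[, c(keycols, "margalef_p", "simpson_p",
                                  "bray_p", "binomial_p")],
                  by = keycols, suffixes = c("", "_clean"))
  responses <- list(
    fc_margalef_p = list(col = "fc_margalef_p", crit = "fold_change_2",
                         clean_p = "margalef_p_clean"),
    fc_simpson_p = list(col = "fc_simpson_p", crit = "fold_change_2",
                        clean_p = "simpson_p_clean"),
    fc_bray_p = list(col = "fc_bray_p", crit = "fold_change_2",
                     clean_p = "bray_p_clean"),
    fc_binomial_p = list(col = "fc_binomial_p", crit = "fold_change_2",
                         clean_p = "binomial_p_clean"),
    delta_nsig_nb_wald = list(col = "delta_nsig_nb_wald", crit = "delta_sig_2"),
    delta_nsig_bias_corrected = list(col = "delta_nsig_bias_corrected",
                                     crit = "delta_sig_2")
  )
  rows <- list()
  for (mode in unique(merged$contam_mode)) {
    sub <- merged[merged$contam_mode == mode, , drop = FALSE]
    for (nm in names(responses)) {
      spec <- responses[[nm]]
      y <- sub[[spec$col]]
      if (spec$crit == "delta_sig_2") y <- abs(y)
      keep <- is.finite(y)
      if (!is.null(spec$clean_p)) {
        keep <- keep & sub[[spec$clean_p]] > .Machine$double.xmin
      }
      if (sum(keep) < 3 || length(unique(sub$contam_level[keep])) < 2) next
      th <- threshold_for_criterion(sub$contam_level[keep], y[keep],
                                    criterion = spec$crit)
      rows[[length(rows) + 1L]] <- data.frame(
        contam_mode = mode, response = nm, criterion = th$criterion,
        slope = th$slope, intercept = th$intercept, n_star = th$n_star,
        n_points = th$n_points, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Tidy false-positive proportions for the two-way ANOVA
#'
#' Expands each false-positive breakdown row into one observation per
#' category, with the category's share of all significant features as the
#' response.
#'
#' @param fp The `fp` table of an [run_experiment()] result.
#' @return Data frame with columns `method`, `category`, `proportion` plus
#'   the design columns.
#' @export
fp_long <- function(fp) {
  if (is.null(fp) || nrow(fp) == 0) stop("no false-positive rows")
  cats <- c("contaminant", "borderline", "random")
  out <- lapply(cats, function(cat) {
    counts <- fp[[paste0("n_", cat)]]
    data.frame(fp[, c("n_per_group", "n_taxa", "sigma2", "replicate",
                      "contam_mode", "contam_level", "method")],
               category = cat,
               proportion = ifelse(fp$n_significant > 0,
                                   counts / fp$n_significant, 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
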