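# shared fixtures and memoised expensive computations

.cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

# a small deterministic two-group matrix with a real group signal
fixture_matrix <- function(n_per_group = 10, n_taxa = 30, sigma2 = 1,
                           seed = 101) {
  cell <- design_cell(n_per_group, n_taxa, sigma2, seed = seed)
  simulate_counts(cell)
}

# hand-built count_matrix from explicit counts
manual_matrix <- function(counts, groups = rep(c("S1", "S2"),
                                               each = ncol(counts) / 2)) {
  count_matrix(counts, groups = groups)
}

# hand-built da_result with prescribed p/q values (for classifier tests)
manual_da <- function(taxon_id, q, method = "nb_wald", alpha = 0.05) {
  out <- data.frame(taxon_id = taxon_id, effect = 0, se = 1,
                    p = q, q = q, significant = q <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  attr(out, "n_significant") <- sum(out$significant)
  class(out) <- c("da_result", "data.frame")
  out
}

# null-simulation raw p-value fractions for both DA tests (shared between
# the module tests and the calibration suite)
null_da_fractions <- function() {
  memoise_fixture("null_da", function() {
    reps <- 200
    fr <- matrix(NA_real_, reps, 2,
                 dimnames = list(NULL, c("nb_wald", "bias_corrected")))
    for (r in seq_len(reps)) {
      cell <- design_cell(50, 100, 0, seed = 40000 + r)
      m <- simulate_counts(cell)
      fr[r, 1] <- mean(nb_wald_test(m)$p <= 0.05)
      fr[r, 2] <- mean(bias_corrected_test(m)$p <= 0.05)
    }
    fr
  })
}

# the reduced evaluation grid used by the scaled-down reproduction suite:
# 3 x 3 x 3 community cells, contamination {1,5,10,100} in both modes,
# 3 replicate seeds
reduced_grid_result <- function() {
  memoise_fixture("reduced_grid", function() {
    cfg <- experiment_config(
      n_per_group = c(10, 30, 60),
      n_taxa = c(10, 100, 1000),
      sigma2 = c(0.1, 10, 100),
      contam_levels = c(0, 1, 5, 10, 100),
      contam_modes = c("unweighted", "weighted"),
      n_replicates = 3,
      master_seed = 1
    )
    suppressWarnings(run_experiment(cfg))
  })
}

# bootstrap percentile CI for a pooled threshold estimate: resample the
# (level, response) points feeding the OLS fit
bootstrap_threshold_ci <- function(levels, response, criterion,
                                   n_boot = 1000, seed = 1,
                                   probs = c(0.025, 0.975)) {
  set.seed(seed)
  n <- length(levels)
  est <- replicate(n_boot, {
    ix <- sample.int(n, n, replace = TRUE)
    th <- tryCatch(
      threshold_for_criterion(levels[ix], response[ix], criterion),
      error = function(e) NULL)
    if (is.null(th)) NA_real_ else th$n_star
  })
  stats::quantile(est, probs, na.rm = TRUE)
}
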