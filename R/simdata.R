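#' Derive a deterministic child seed
#'
#' Stages of the pipeline (model construction, count simulation, contaminant
#' injection, permutation tests) each consume their own RNG seed derived
#' deterministically from a master seed plus a sequence of integer or string
#' coordinates, so that any single stage of any grid cell can be re-run in
#' isolation and reproduce its output bit-for-bit. The derivation is a simple
#' multiplicative-congruential fold over the coordinates, kept inside the
#' 32-bit signed integer range.
#'
#' @param master Integer master seed.
#' @param ... Integer or character coordinates (cell index, stage name, ...).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- as.numeric(master) %% m
  for (k in list(...)) {
    if (is.character(k)) {
      cp <- utf8ToInt(k)
      k <- sum(cp * seq_along(cp)) %% m
    }
    k <- as.numeric(k) %% m
    # 48271 is the MINSTD multiplier; any full-period multiplier would do
    x <- (x * 48271 + k + 1) %% m
  }
  as.integer(x)
}

#' Define one cell of the simulation design grid
#'
#' @param n_per_group Samples per experimental group (>= 2).
#' @param n_taxa Maximum number of taxa in any one sample (>= 1); realised
#'   richness can be lower because simulated counts may be all zero for a
#'   taxon.
#' @param sigma2 Non-negative variance of the per-taxon, per-group random
#'   effect controlling between-group dissimilarity.
#' @param contam_level Number of contaminant taxa to inject (0 when
#'   `contam_mode` is `"none"`).
#' @param contam_mode One of `"none"`, `"unweighted"` (group-balanced
#'   contamination) or `"weighted"` (group-biased contamination).
#' @param seed Integer seed for this cell.
#' @return A list of class `design_cell`.
#' @export
design_cell <- function(n_per_group, n_taxa, sigma2,
                        contam_level = 0L,
                        contam_mode = c("none", "unweighted", "weighted"),
                        seed = 1L) {
  contam_mode <- match.arg(contam_mode)
  n_per_group <- as.integer(n_per_group)
  n_taxa <- as.integer(n_taxa)
  contam_level <- as.integer(contam_level)
  if (is.na(n_per_group) || n_per_group < 2) stop("`n_per_group` must be >= 2")
  if (is.na(n_taxa) || n_taxa < 1) stop("`n_taxa` must be >= 1")
  if (!is.finite(sigma2) || sigma2 < 0) stop("`sigma2` must be >= 0")
  if (is.na(contam_level) || contam_level < 0) stop("`contam_level` must be >= 0")
  if ((contam_level == 0L) != (contam_mode == "none")) {
    stop("`contam_level` must be 0 exactly when `contam_mode` is \"none\"")
  }
  structure(
    list(n_per_group = n_per_group, n_taxa = n_taxa, sigma2 = sigma2,
         contam_level = contam_level, contam_mode = contam_mode,
         seed = as.integer(seed)),
    class = "design_cell"
  )
}

#' Build the factorial simulation grid
#'
#' Forms the Cartesian product of the three community axes (samples per
#' group, maximum taxa, group-effect variance), crossed with the requested
#' contamination levels and modes. A contamination level of 0 always maps to
#' mode `"none"` and appears once per base cell regardless of how many modes
#' are requested. Each cell receives a deterministic child seed derived from
#' the master seed and the cell's coordinates.
#'
#' @param n_per_group,n_taxa,sigma2 Numeric vectors: the community axes.
#'   Defaults are the grid used throughout the package's own study:
#'   `{10, 30, 60, 120, 240}` samples per group, `{10, 100, 1000, 2000,
#'   5000}` taxa, variances `{0.1, 1, 10, 50, 100}`.
#' @param contam_levels Integer vector of contaminant counts (default `0`,
#'   i.e. no contamination axis).
#' @param contam_modes Character vector among `"unweighted"`, `"weighted"`;
#'   ignored for level 0.
#' @param master_seed Integer master seed.
#' @param drop_cells Optional integer vector of base-cell indices (1-based,
#'   in row-major order of the expanded community grid) to exclude.
#' @return A list of `design_cell` objects.
#' @export
make_grid <- function(n_per_group = c(10, 30, 60, 120, 240),
                      n_taxa = c(10, 100, 1000, 2000, 5000),
                      sigma2 = c(0.1, 1, 10, 50, 100),
                      contam_levels = 0L,
                      contam_modes = c("unweighted", "weighted"),
                      master_seed = 1L,
                      drop_cells = NULL) {
  check_axis <- function(x, name) {
    if (length(x) == 0) stop(sprintf("grid axis `%s` is empty", name))
    if (anyDuplicated(x)) stop(sprintf("grid axis `%s` has duplicate values", name))
    x
  }
  check_axis(n_per_group, "n_per_group")
  check_axis(n_taxa, "n_taxa")
  check_axis(sigma2, "sigma2")
  check_axis(contam_levels, "contam_levels")
  contam_modes <- match.arg(contam_modes, several.ok = TRUE)

  base <- expand.grid(sigma2 = sigma2, n_taxa = n_taxa,
                      n_per_group = n_per_group,
                      KEEP.OUT.ATTRS = FALSE)
  base <- base[, c("n_per_group", "n_taxa", "sigma2")]
  if (!is.null(drop_cells)) {
    if (any(drop_cells < 1 | drop_cells > nrow(base))) {
      stop("`drop_cells` out of range")
    }
    base <- base[-drop_cells, , drop = FALSE]
  }

  cells <- list()
  for (i in seq_len(nrow(base))) {
    combos <- list()
    for (lev in sort(unique(as.integer(contam_levels)))) {
      if (lev == 0L) {
        combos[[length(combos) + 1L]] <- list(level = 0L, mode = "none")
      } else {
        for (mode in contam_modes) {
          combos[[length(combos) + 1L]] <- list(level = lev, mode = mode)
        }
      }
    }
    for (cmb in combos) {
      cells[[length(cells) + 1L]] <- design_cell(
        n_per_group = base$n_per_group[i],
        n_taxa = base$n_taxa[i],
        sigma2 = base$sigma2[i],
        contam_level = cmb$level,
        contam_mode = cmb$mode,
        seed = child_seed(master_seed, i, cmb$mode, cmb$level)
      )
    }
  }
  cells
}

#' Tabulate a grid as a data frame
#'
#' @param cells List of `design_cell` objects as produced by [make_grid()].
#' @return A data frame with one row per cell.
#' @export
grid_table <- function(cells) {
  do.call(rbind, lapply(cells, function(cl) {
    data.frame(n_per_group = cl$n_per_group, n_taxa = cl$n_taxa,
               sigma2 = cl$sigma2, contam_level = cl$contam_level,
               contam_mode = cl$contam_mode, seed = cl$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Community model for count simulation
#'
#' Per-taxon log-scale abundance intercepts plus a shared negative-binomial
#' dispersion and the group-effect variance. The default intercept
#' distribution, Normal(mean 2, sd 2) on the natural-log scale, yields a
#' realistic rank-abundance curve: a handful of dominant taxa with expected
#' counts in the hundreds alongside a substantial tail of rare taxa with
#' expected counts below one.
#'
#' @param cell A `design_cell` (supplies `n_taxa` and `sigma2`).
#' @param intercept_mean,intercept_sd Parameters of the Normal intercept
#'   distribution on the log scale.
#' @param dispersion Negative-binomial dispersion `phi` (> 0), parameterised
#'   so that `Var(Y) = mu + phi * mu^2`.
#' @param seed Integer seed; defaults to a child of the cell's seed so the
#'   model is reproducible per cell.
#' @return A list of class `community_model` with elements `intercepts`,
#'   `dispersion`, `sigma2`.
#' @export
default_model <- function(cell, intercept_mean = 2, intercept_sd = 2,
                          dispersion = 0.5,
                          seed = child_seed(cell$seed, "model")) {
  if (!inherits(cell, "design_cell")) stop("expected a `design_cell`")
  if (!is.finite(dispersion) || dispersion <= 0) stop("`dispersion` must be > 0")
  set.seed(seed)
  intercepts <- stats::rnorm(cell$n_taxa, intercept_mean, intercept_sd)
  community_model(intercepts, dispersion, cell$sigma2)
}

#' @rdname default_model
#' @param intercepts Numeric vector of finite per-taxon log-scale intercepts.
#' @param sigma2 Non-negative group-effect variance.
#' @export
community_model <- function(intercepts, dispersion = 0.5, sigma2 = 0) {
  if (any(!is.finite(intercepts))) stop("`intercepts` must be finite")
  if (!is.finite(dispersion) || dispersion <= 0) stop("`dispersion` must be > 0")
  if (!is.finite(sigma2) || sigma2 < 0) stop("`sigma2` must be >= 0")
  structure(list(intercepts = as.numeric(intercepts),
                 dispersion = dispersion, sigma2 = sigma2),
            class = "community_model")
}

#' Simulate a two-group negative-binomial count matrix
#'
#' For each taxon `t` and group `g` a random effect `b[t, g] ~ Normal(0,
#' sigma2)` is drawn independently, the group mean is `mu[t, g] = exp(alpha_t
#' + b[t, g])`, and each sample's count is drawn from a negative binomial
#' with that mean and dispersion `phi` (`Var = mu + phi * mu^2`). Because the
#' two group effects are independent per taxon, `sigma2` acts as a clean dial
#' for expected between-group dissimilarity, from near-identical communities
#' at 0.1 to essentially non-overlapping ones at 100. Some taxa may come out
#' all-zero, so the realised richness is at most `n_taxa`.
#'
#' @param cell A `design_cell`.
#' @param model A `community_model`; defaults to [default_model()] for the
#'   cell. Its `intercepts` length must equal `cell$n_taxa`.
#' Counts are sampled through the negative binomial's Gamma-Poisson
#' representation: `lambda ~ Gamma(shape 1/phi, mean mu)`, `Y ~
#' Poisson(lambda)`. When the log-normal random effect pushes an intensity
#' beyond the integer range (possible at `sigma2` of 50-100), the Poisson
#' step is skipped and `lambda` is rounded directly -- at that magnitude the
#' Poisson noise is a negligible relative perturbation, and such counts are
#' meaningful on the relative (compositional) scale only.
#'
#' @param seed Integer seed; defaults to a child of the cell's seed.
#' @return A [count_matrix()] with `2 * n_per_group` samples, groups labelled
#'   `"S1"` and `"S2"`.
#' @export
simulate_counts <- function(cell, model = default_model(cell),
                            seed = child_seed(cell$seed, "counts")) {
  if (!inherits(cell, "design_cell")) stop("expected a `design_cell`")
  if (!inherits(model, "community_model")) stop("expected a `community_model`")
  if (length(model$intercepts) != cell$n_taxa) {
    stop(sprintf("model has %d intercepts but cell requires %d taxa",
                 length(model$intercepts), cell$n_taxa))
  }
  n_t <- cell$n_taxa
  n_s <- cell$n_per_group
  set.seed(seed)
  b <- matrix(stats::rnorm(2L * n_t, 0, sqrt(model$sigma2)), nrow = n_t)
  mu <- exp(model$intercepts + b) # n_taxa x 2 group means
  size <- 1 / model$dispersion
  mu_all <- mu[, rep(1:2, each = n_s)] # n_taxa x 2 n_per_group
  lambda <- matrix(
    stats::rgamma(n_t * 2L * n_s, shape = size, rate = size / mu_all),
    nrow = n_t)
  counts <- lambda
  small <- lambda < 2^30
  counts[small] <- stats::rpois(sum(small), lambda[small])
  counts[!small] <- round(lambda[!small])
  groups <- factor(rep(c("S1", "S2"), each = n_s), levels = c("S1", "S2"))
  count_matrix(
    counts,
    taxon_ids = paste0("taxon_", seq_len(n_t)),
    sample_ids = paste0(rep(c("S1", "S2"), each = n_s), "_",
                        rep(seq_len(n_s), 2L)),
    groups = groups
  )
}
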