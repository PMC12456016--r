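#' Bray-Curtis dissimilarity matrix
#'
#' Abundance-weighted dissimilarity `d(x, y) = sum(|x - y|) / sum(x + y)`
#' over taxa, computed with [vegan::vegdist()]. Bounded in `[0, 1]`, 0 for
#' identical samples, 1 for samples sharing no taxa.
#'
#' @param m A [count_matrix()] with at least two samples and no all-zero
#'   sample.
#' @return A `dist` object over samples with attribute `metric_name =
#'   "bray_curtis"`.
#' @export
bray_curtis <- function(m) {
  stopifnot_count_matrix(m)
  check_dist_input(m, forbid_empty = TRUE)
  d <- vegan::vegdist(t(m$counts), method = "bray")
  attr(d, "metric_name") <- "bray_curtis"
  d
}

#' Binomial-deviance dissimilarity matrix
#'
#' The deviance-based dissimilarity of community ecology, used here as the
#' "unweighted" beta-diversity metric: for each taxon with joint count
#' `n_i = x_i + y_i > 0`, the scaled deviance
#' `[x_i log(x_i / n_i) + y_i log(y_i / n_i) - n_i log(1/2)] / n_i`
#' (with `0 log 0 = 0`) is summed over taxa; double-zero taxa contribute
#' nothing. Computed with [vegan::vegdist()].
#'
#' @param m A [count_matrix()] with at least two samples.
#' @return A `dist` object over samples with attribute `metric_name =
#'   "binomial"`.
#' @export
binomial_dissimilarity <- function(m) {
  stopifnot_count_matrix(m)
  check_dist_input(m, forbid_empty = FALSE)
  d <- vegan::vegdist(t(m$counts), method = "binomial")
  attr(d, "metric_name") <- "binomial"
  d
}

check_dist_input <- function(m, forbid_empty) {
  if (ncol(m$counts) < 2) stop("need at least 2 samples")
  if (forbid_empty && any(colSums(m$counts) == 0)) {
    stop("all-zero sample: dissimilarity undefined")
  }
  invisible(m)
}

#' Two-group PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance for a one-way, two-level
#' design. The pseudo-F is computed from the squared-distance partition:
#' total sum of squares `SS_T = sum over all pairs d^2 / n`, within-group
#' `SS_W = sum over groups of (within-group pair d^2 sums / group size)`,
#' and `F = (SS_T - SS_W) / (SS_W / (n - 2))` (one between-group degree of
#' freedom). Significance is assessed by permuting group labels; the
#' add-one convention `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`
#' bounds p below by `1/(n_permutations + 1)` (0.001 at 999 permutations).
#'
#' @param d A `dist` object or square symmetric matrix of dissimilarities.
#' @param groups Two-level factor over the samples of `d`; each level needs
#'   at least 2 members.
#' @param n_permutations Number of random label permutations (default 999).
#' @param seed Integer seed making the permutation sequence reproducible.
#' @return A list of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != n) stop("`groups` must cover all samples")
  if (nlevels(groups) != 2) stop("`groups` must have two levels")
  if (any(tabulate(groups) < 2)) stop("each group needs at least 2 members")
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)

  g1 <- as.integer(groups) == 1L
  f_obs <- permanova_f(d2, g1, n, ss_total)

  set.seed(seed)
  n_g1 <- sum(g1)
  n_g2 <- n - n_g1
  # one indicator column per permutation, plus the observed labelling in
  # column 1 so observed and permuted statistics share one arithmetic
  # route (exact ties, e.g. the complementary labelling, then compare
  # consistently); SS_W for all columns comes from a single matrix product
  z_mat <- matrix(0, n, n_permutations + 1L)
  z_mat[g1, 1L] <- 1
  for (i in seq_len(n_permutations)) {
    z_mat[sample.int(n, n_g1), i + 1L] <- 1
  }
  v <- d2 %*% z_mat
  r <- rowSums(d2)
  ssw1 <- colSums(z_mat * v) / (2 * n_g1)
  ssw2 <- (sum(r) - colSums(z_mat * r) - colSums(v) + colSums(z_mat * v)) /
    (2 * n_g2)
  ssw <- ssw1 + ssw2
  f_all <- (ss_total - ssw) / (ssw / (n - 2))
  tol <- 1e-12 * max(1, abs(f_all[1L]))
  p <- (1 + sum(f_all[-1L] >= f_all[1L] - tol)) / (1 + n_permutations)
  structure(list(pseudo_F = f_obs, p_value = p,
                 n_permutations = n_permutations),
            class = "permanova_result")
}

# pseudo-F for a two-group labelling given the squared-distance matrix
permanova_f <- function(d2, g1, n, ss_total) {
  n1 <- sum(g1)
  n2 <- n - n1
  ss_within <- sum(d2[g1, g1]) / (2 * n1) + sum(d2[!g1, !g1]) / (2 * n2)
  ss_between <- ss_total - ss_within
  (ss_between / 1) / (ss_within / (n - 2))
}

#' Exhaustive-permutation PERMANOVA p-value
#'
#' For small designs, evaluates the pseudo-F under every distinct assignment
#' of samples to the two groups (at the observed group sizes) and returns
#' the exact permutation p-value `#{F >= F_obs} / #assignments`. Used as a
#' reference for the Monte-Carlo permutation test.
#'
#' @inheritParams permanova
#' @return List with `pseudo_F`, `p_value`, `n_assignments`.
#' @export
permanova_exact <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- droplevels(as.factor(groups))
  n1 <- sum(as.integer(groups) == 1L)
  d2 <- dm^2
  ss_total <- sum(d2) / (2 * n)
  f_obs <- permanova_f(d2, as.integer(groups) == 1L, n, ss_total)
  combos <- utils::combn(n, n1)
  f_all <- apply(combos, 2L, function(ix) {
    z <- logical(n)
    z[ix] <- TRUE
    permanova_f(d2, z, n, ss_total)
  })
  list(pseudo_F = f_obs,
       p_value = mean(f_all >= f_obs - 1e-12),
       n_assignments = ncol(combos))
}
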