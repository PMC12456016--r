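test_that("size factors reproduce the median-of-ratios definition", {
  # identical columns: all factors 1
  m_id <- manual_matrix(matrix(rep(c(4L, 9L, 2L), 6), nrow = 3))
  expect_equal(unname(size_factors(m_id)), rep(1, 6))

  # doubling one column doubles its factor relative to the others
  x <- matrix(rep(c(4L, 9L, 2L), 6), nrow = 3)
  x[, 3] <- x[, 3] * 2L
  sf <- size_factors(manual_matrix(x))
  expect_equal(unname(sf[3] / sf[1]), 2)

  # brute-force evaluation of the definition on a random positive matrix
  # (odd number of reference taxa so the median is a unique element)
  set.seed(5)
  y <- matrix(rpois(9 * 10, 20) + 1L, nrow = 9)
  m <- manual_matrix(y)
  sf <- size_factors(m)
  gm <- apply(y, 1, function(r) exp(mean(log(r))))
  raw <- apply(y / gm, 2, median)
  expect_equal(unname(sf), raw / exp(mean(log(raw))))
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("size factors agree with the DESeq2 reference on positive data", {
  set.seed(6)
  y <- matrix(rpois(30 * 12, 50) + 1L, nrow = 30)
  m <- manual_matrix(y)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(y)
  # same factors up to the geometric-mean-1 rescaling convention
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("sparse matrices fall back to the pseudo-reference with a warning", {
  set.seed(7)
  y <- matrix(rpois(20 * 8, 2), nrow = 20)
  y[cbind(seq_len(20), rep_len(1:8, 20))] <- 0L # every taxon has a zero
  expect_warning(sf <- size_factors(manual_matrix(y)), "pseudo-reference")
  expect_true(all(sf > 0))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p and monotone thinning of the significant set
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_lte(sum(q <= 0.01), sum(q <= 0.05))
})

test_that("NB Wald test flags no effect for constant taxa and needs two groups", {
  # identical columns: size factors are exactly 1 and every taxon has
  # identical counts in all samples, so effects vanish exactly
  v <- c(7L, 30L, 2L, 150L, 12L, 0L, 5L, 64L, 1L, 9L)
  m <- manual_matrix(matrix(rep(v, 12), ncol = 12))
  res <- nb_wald_test(m)
  expect_true(all(abs(res$effect) < 1e-10))
  expect_true(all(!res$significant))
  expect_equal(attr(res, "method"), "nb_wald")
  expect_equal(n_significant(res), sum(res$q <= 0.05))
  expect_equal(res$p[6], 1) # all-zero taxon gets p = 1 by convention
})

test_that("both DA tests hold their nominal type-I error under the null", {
  fr <- null_da_fractions()
  n_tests <- nrow(fr) * 100
  half <- 2.576 * sqrt(0.05 * 0.95 / n_tests)
  expect_lt(abs(mean(fr[, "nb_wald"]) - 0.05), half)
  expect_lt(abs(mean(fr[, "bias_corrected"]) - 0.05), half)
})

test_that("a strong spiked effect is detected reliably", {
  # the spiked taxon gets a fixed, comfortably observable abundance
  # (log-mean 3, ~20 expected counts); the other 99 intercepts are drawn
  # from the default Normal(2, 2)
  hits_nb <- hits_bc <- logical(100)
  for (r in seq_len(100)) {
    cell <- design_cell(30, 100, 0, seed = 80000 + r)
    model <- default_model(cell)
    model$intercepts[1] <- 3
    m <- simulate_counts(cell, model)
    m$counts[1, m$groups == "S2"] <- m$counts[1, m$groups == "S2"] * 8L
    res_nb <- nb_wald_test(m)
    res_bc <- bias_corrected_test(m)
    hits_nb[r] <- res_nb$q[1] <= 0.05
    hits_bc[r] <- which.min(res_bc$q) == 1
  }
  expect_gte(mean(hits_nb), 0.95) # 8-fold change at n = 30/group
  expect_gte(mean(hits_bc), 0.95) # spiked taxon has the smallest q
})

test_that("bias correction absorbs a global compositional shift", {
  # degenerate case: within-group counts constant, group 2 = 4 x group 1
  # for every taxon; the common factor is pure sampling fraction and the
  # residual effects are only the pseudocount's curvature
  v <- c(100L, 400L, 1000L, 50L, 800L)
  x <- cbind(matrix(rep(v, 6), ncol = 6), matrix(rep(4L * v, 6), ncol = 6))
  res <- bias_corrected_test(manual_matrix(x))
  expect_equal(n_significant(res), 0)
  expect_lt(max(abs(res$effect)), 0.02) # log(4) = 1.386 fully absorbed

  # noisy case: a 4-fold shift of every taxon leaves effects near zero
  set.seed(91)
  y1 <- matrix(rpois(50 * 10, 500), ncol = 10)
  y2 <- matrix(rpois(50 * 10, 2000), ncol = 10)
  res2 <- bias_corrected_test(manual_matrix(cbind(y1, y2)))
  expect_lt(max(abs(res2$effect)), 0.1) # far below the log(4) shift
  expect_equal(n_significant(res2), 0)
})

test_that("DA results are invariant to sample order and label swaps", {
  m <- fixture_matrix(n_per_group = 10, n_taxa = 30, sigma2 = 1, seed = 71)
  set.seed(72)
  perm <- sample(seq_len(20))
  m_perm <- count_matrix(m$counts[, perm], groups = m$groups[perm])
  m_swap <- count_matrix(m$counts,
                         groups = factor(ifelse(m$groups == "S1", "S2", "S1"),
                                         levels = c("S1", "S2")))
  for (f in list(nb_wald_test, bias_corrected_test)) {
    res <- f(m)
    expect_equal(f(m_perm)$p, res$p, tolerance = 1e-9)
    swapped <- f(m_swap)
    expect_equal(swapped$p, res$p, tolerance = 1e-9)
    expect_equal(swapped$effect, -res$effect, tolerance = 1e-9)
  }
  expect_error(nb_wald_test(count_matrix(m$counts[, 1:2, drop = FALSE],
                                         groups = c("S1", "S2"))),
               "at least 2")
})

test_that("the size factor absorbs an exact rescaling of one sample", {
  # abundant taxa so the Poisson component of the variance is negligible
  cell <- design_cell(8, 25, 0.5, seed = 81)
  model <- community_model(rep(5, 25), dispersion = 0.5, sigma2 = 0.5)
  m <- simulate_counts(cell, model)
  res <- nb_wald_test(m)
  sf <- size_factors(m)
  m2 <- m
  m2$counts[, 5] <- m2$counts[, 5] * 3L
  sf2 <- size_factors(m2)
  # the tripled sample's factor triples relative to every other sample
  expect_equal(unname(sf2[5] / sf2[-5] / (sf[5] / sf[-5])), rep(3, 15),
               tolerance = 1e-12)
  # effects and p-values match up to the small perturbation of the
  # per-taxon dispersion estimate by the shifted absolute count scale
  # (the Poisson component of the NB variance is not scale-free)
  res2 <- nb_wald_test(m2)
  expect_equal(res2$effect, res$effect, tolerance = 1e-2)
  expect_equal(res2$p, res$p, tolerance = 5e-2)
})
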