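test_that("Margalef richness matches its closed form", {
  expect_equal(margalef(c(5)), 0)                       # one taxon
  expect_equal(margalef(c(rep(10, 10))), 9 / log(100))  # S=10, N=100
  expect_equal(margalef(c(1)), 0)                       # N=1 convention
  expect_error(margalef(c(0, 0)), "all-zero")
  # strictly increasing in S at fixed N
  vals <- sapply(1:10, function(s) margalef(c(rep(1, s), 100 - s)))
  expect_true(all(diff(vals) > 0))
})

test_that("Simpson index matches hand evaluation and is scale-invariant", {
  expect_equal(simpson(c(7)), 0)
  expect_equal(simpson(rep(3, 4)), 0.75)
  expect_equal(simpson(c(1, 2, 3)), 1 - 14 / 36)
  expect_equal(simpson(c(1, 2, 3), form = "dominance"), 14 / 36)
  expect_equal(simpson(c(1, 2, 3)), simpson(c(10, 20, 30)))
  expect_error(simpson(c(0, 0)), "all-zero")
  # agrees with the community-ecology reference implementation
  set.seed(1)
  x <- rpois(20, 5) + 1
  expect_equal(simpson(x), unname(vegan::diversity(x, "simpson")))
})

test_that("paired t-test matches the textbook formula and rejects degenerate input", {
  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_equal(paired_t_test(c(2, 1, 2, 1), c(1, 2, 1, 2)), 1)
  s1 <- c(3.1, 4.5, 2.2, 5.0, 3.3)
  s2 <- c(2.0, 4.1, 2.5, 4.0, 2.9)
  d <- s1 - s2
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_stat), df = length(d) - 1)
  expect_equal(paired_t_test(s1, s2), p_hand)
})

test_that("Bray-Curtis matches hand values and stays within [0, 1]", {
  m_id <- manual_matrix(cbind(c(1, 2), c(1, 2), c(3, 1), c(3, 1)))
  d_id <- as.matrix(bray_curtis(m_id))
  expect_equal(d_id[1, 2], 0)
  m_disj <- manual_matrix(cbind(c(5, 0), c(4, 0), c(0, 3), c(0, 7)))
  expect_equal(as.matrix(bray_curtis(m_disj))[1, 3], 1)
  m_hand <- manual_matrix(cbind(c(2, 2), c(1, 3), c(1, 1), c(1, 1)))
  expect_equal(as.matrix(bray_curtis(m_hand))[1, 2], 0.25)

  m_rand <- fixture_matrix(seed = 55)
  d <- as.matrix(bray_curtis(m_rand))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(bray_curtis(manual_matrix(cbind(c(0, 0), c(1, 1), c(1, 0),
                                               c(0, 1)))), "all-zero")
})

test_that("binomial dissimilarity matches hand values and ignores double zeros", {
  m <- manual_matrix(cbind(c(1, 0), c(0, 1), c(2, 2), c(2, 2)))
  d <- as.matrix(binomial_dissimilarity(m))
  expect_equal(d[1, 2], 2 * log(2))
  expect_equal(d[3, 4], 0)
  # appending taxa absent from both samples leaves distances unchanged
  zero_rows <- matrix(0, 3, 4,
                      dimnames = list(paste0("absent_", 1:3), NULL))
  m_aug <- manual_matrix(rbind(m$counts, zero_rows))
  expect_equal(as.matrix(binomial_dissimilarity(m_aug)), d)
})

test_that("distance matrices satisfy metric-shape properties on random data", {
  for (seed in c(1, 2, 3)) {
    m <- fixture_matrix(n_per_group = 6, n_taxa = 25, seed = seed)
    for (f in list(bray_curtis, binomial_dissimilarity)) {
      d <- as.matrix(f(m))
      expect_true(all(d >= 0))
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
    }
  }
})

test_that("PERMANOVA pseudo-F agrees with the vegan reference", {
  m <- fixture_matrix(n_per_group = 8, n_taxa = 40, sigma2 = 1, seed = 9)
  d <- bray_curtis(m)
  ours <- permanova(d, m$groups, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = m$groups),
                        permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA respects its p-value conventions", {
  # two tight, well-separated clusters: observed F exceeds every permutation
  set.seed(42)
  x <- cbind(matrix(rep(c(0, 100), 10), nrow = 2),   # S1 profile (0, 100)
             matrix(rep(c(100, 0), 10), nrow = 2)) + # S2 profile (100, 0)
    matrix(rpois(40, 2), nrow = 2)
  m <- manual_matrix(x)
  res <- permanova(bray_curtis(m), m$groups, n_permutations = 999, seed = 2)
  expect_equal(res$p_value, 0.001) # the add-one floor (1+0)/(1+999)
  # pseudo-F invariant to relabelling the groups
  flipped <- factor(ifelse(m$groups == "S1", "S2", "S1"))
  res_flip <- permanova(bray_curtis(m), flipped, n_permutations = 99, seed = 2)
  expect_equal(res$pseudo_F, res_flip$pseudo_F)
  # reproducible given the seed
  expect_identical(res, permanova(bray_curtis(m), m$groups,
                                  n_permutations = 999, seed = 2))
})

test_that("Monte-Carlo PERMANOVA p agrees with exhaustive enumeration at n = 6", {
  set.seed(14)
  x <- matrix(rpois(5 * 6, 10), nrow = 5)
  m <- manual_matrix(x, groups = rep(c("S1", "S2"), each = 3))
  d <- bray_curtis(m)
  exact <- permanova_exact(d, m$groups)
  expect_equal(exact$n_assignments, 20)
  mc <- permanova(d, m$groups, n_permutations = 4999, seed = 8)
  # sampling error of the permutation estimate at 4999 draws
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4999)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / 5000)
})

test_that("PERMANOVA type-I error is nominal under random labels", {
  reps <- 500
  pvals <- vapply(seq_len(reps), function(r) {
    set.seed(70000 + r)
    x <- matrix(rpois(20 * 10, 5), nrow = 20)
    m <- manual_matrix(x)
    permanova(bray_curtis(m), m$groups, n_permutations = 199,
              seed = r)$p_value
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), half)
})

test_that("PERMANOVA input validation", {
  m <- fixture_matrix(n_per_group = 4, n_taxa = 10)
  d <- bray_curtis(m)
  expect_error(permanova(d, rep("S1", 8)), "two levels")
  expect_error(permanova(d, c("S1", rep("S2", 7))), "at least 2")
})
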