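test_that("neglog10 and fold-change transforms behave as defined", {
  expect_equal(neglog10(1), 0)
  expect_equal(neglog10(0.001), 3)
  expect_equal(neglog10(0.05), 1.301, tolerance = 1e-3)
  expect_error(neglog10(0), "\\(0, 1\\]")
  expect_error(neglog10(-0.1), "\\(0, 1\\]")

  expect_equal(p_fold_change(0.05, 0.05), 1)
  expect_equal(p_fold_change(0.10, 0.05), 2)
  expect_equal(p_fold_change(0.01, 0.05), 0.2)
  expect_error(p_fold_change(0.5, 0), "> 0")
})

test_that("correlate matches the Pearson formula and checks normality", {
  df <- data.frame(x = 1:10, y = 2 * (1:10))
  res <- suppressWarnings(correlate(df, "x", "y"))
  expect_equal(res$r, 1)

  set.seed(3)
  df2 <- data.frame(x = rnorm(15), y = rnorm(15))
  res2 <- correlate(df2, "x", "y")
  r_hand <- sum((df2$x - mean(df2$x)) * (df2$y - mean(df2$y))) /
    sqrt(sum((df2$x - mean(df2$x))^2) * sum((df2$y - mean(df2$y))^2))
  expect_equal(res2$r, r_hand)
  expect_true(is.finite(res2$normality_p))

  expect_error(correlate(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "degenerate")
  # non-normal outcome attaches a warning but stays Pearson
  df3 <- data.frame(x = 1:40, y = exp(rnorm(40, sd = 3)))
  expect_warning(res3 <- correlate(df3, "x", "y"), "normality")
  expect_true(is.finite(res3$r))
})

test_that("normality check is calibrated and has power against skew", {
  reject_normal <- vapply(1:200, function(r) {
    set.seed(10000 + r)
    normality_check(rnorm(500)) <= 0.05
  }, logical(1))
  half <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(reject_normal) - 0.05), half)

  reject_skew <- vapply(1:200, function(r) {
    set.seed(20000 + r)
    normality_check(rexp(500)) <= 0.05
  }, logical(1))
  expect_gt(mean(reject_skew), 0.99)

  expect_error(normality_check(rep(2, 10)), "constant")
})

test_that("threshold solves the fitted line for the criterion value", {
  lv <- c(0, 1, 5, 10, 100)
  th <- threshold_for_criterion(lv, 1 + 0.2 * lv, "fold_change_2")
  expect_equal(th$n_star, 5)
  expect_equal(th$slope, 0.2)

  flat <- threshold_for_criterion(lv, rep(1, 5), "fold_change_2")
  expect_true(is.na(flat$n_star))

  high <- threshold_for_criterion(lv, 3 + 0.1 * lv, "delta_sig_2")
  expect_equal(high$n_star, 0) # intercept already beyond the criterion

  expect_error(threshold_for_criterion(rep(5, 4), 1:4), "distinct")
})

test_that("threshold recovery from noisy planted lines", {
  lv <- rep(c(1, 5, 10, 100), each = 5)
  est <- vapply(1:1000, function(r) {
    set.seed(30000 + r)
    y <- 1 + 0.2 * lv + rnorm(length(lv), sd = 0.3)
    threshold_for_criterion(lv, y, "fold_change_2")$n_star
  }, numeric(1))
  expect_lt(abs(median(est) - 5) / 5, 0.05)
})

test_that("false-positive classification follows the FDR strata", {
  clean <- manual_da(paste0("t", 1:6), q = c(0.01, 0.07, 0.5, 0.2, 0.09, 0.9))
  # contaminated result: t1 still significant (true positive), t2 and t5
  # (borderline in clean), t3 (random), plus contaminants C1 significant,
  # C2 not
  cont <- manual_da(c(paste0("t", 1:6), "C1", "C2"),
                    q = c(0.01, 0.04, 0.02, 0.5, 0.03, 0.9, 0.001, 0.8))
  fb <- classify_false_positives(clean, cont, c("C1", "C2"))
  expect_equal(unname(fb$counts["contaminant"]), 1)
  expect_equal(unname(fb$counts["borderline"]), 2) # clean q 0.07 and 0.09
  expect_equal(unname(fb$counts["random"]), 1)     # clean q 0.5
  expect_equal(fb$n_false_positive, 4)
  expect_equal(fb$n_significant, 5)
  expect_equal(fb$fp_proportion, 4 / 5)

  # nothing newly significant and no significant contaminants
  cont_null <- manual_da(c(paste0("t", 1:6), "C1"),
                         q = c(0.01, 0.5, 0.5, 0.5, 0.5, 0.9, 0.6))
  fb0 <- classify_false_positives(clean, cont_null, "C1")
  expect_equal(unname(fb0$counts), c(0, 0, 0))
  expect_equal(fb0$fp_proportion, 0)

  # clean result must not contain injected taxa
  expect_error(classify_false_positives(clean, cont, "t1"), "contain")
})

test_that("two-way ANOVA decomposition matches hand-computed sums of squares", {
  # balanced 2 x 3 design, 2 replicates per cell
  d <- expand.grid(method = c("A", "B"),
                   category = c("c1", "c2", "c3"),
                   rep = 1:2)
  set.seed(4)
  d$proportion <- 0.1 + 0.05 * (d$method == "B") +
    0.02 * as.integer(d$category) + rnorm(nrow(d), sd = 0.01)
  tab <- fp_anova(d)
  # hand decomposition
  y <- d$proportion
  gm <- mean(y)
  mm <- tapply(y, d$method, mean)
  cm <- tapply(y, d$category, mean)
  cellm <- tapply(y, interaction(d$method, d$category), mean)
  ss_m <- 6 * sum((mm - gm)^2)
  ss_c <- 4 * sum((cm - gm)^2)
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_int <- ss_cells - ss_m - ss_c
  expect_equal(tab$sum_sq[tab$term == "method"], ss_m, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "category"], ss_c, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$term == "method:category"], ss_int,
               tolerance = 1e-10)

  # no between-cell variation at all: F = 0, p = 1
  d2 <- d
  d2$proportion <- ifelse(d2$rep == 1, 0.1, 0.2) # varies only within cells
  tab2 <- fp_anova(d2)
  expect_true(all(tab2$F[1:3] < 1e-20))
  expect_true(all(tab2$p[1:3] > 0.999))

  # a strong injected method effect is detected
  expect_lt(tab$p[tab$term == "method"], 0.01)
  expect_error(fp_anova(d[d$method == "A", ]), "2 levels")
})

test_that("a zero-contamination experiment is the identity for the evaluation layer", {
  cfg <- experiment_config(n_per_group = 5, n_taxa = 15, sigma2 = c(0.1, 1),
                           contam_levels = 0, n_replicates = 1,
                           master_seed = 3, n_permutations = 99)
  res <- run_experiment(cfg)
  expect_null(res$fp)
  oc <- res$outcomes
  expect_true(all(oc$contam_mode == "none"))
  expect_true(all(oc$fc_margalef_p == 1))
  expect_true(all(oc$fc_bray_p == 1))
  expect_true(all(oc$delta_nsig_nb_wald == 0))
  expect_true(all(oc$delta_nsig_bias_corrected == 0))
  expect_error(threshold_table(oc), "no contaminated rows")
})

test_that("experiments are byte-identical across reruns", {
  cfg <- experiment_config(n_per_group = 5, n_taxa = 15, sigma2 = 1,
                           contam_levels = c(0, 5), n_replicates = 2,
                           master_seed = 11, n_permutations = 99)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(r1$fp, r2$fp)
})
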