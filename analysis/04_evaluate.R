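#!/usr/bin/env Rscript
# Stage 4: the inference layer over the experiment tables written by
# analysis/03_run_experiment.R — correlations of outcomes with design
# parameters, contaminant-impact thresholds, and the false-positive
# breakdown.
#   Rscript analysis/04_evaluate.R

library(contamsim)

in_dir <- "results/experiment"
out_dir <- "results/evaluation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
oc <- read.csv(file.path(in_dir, "outcomes.csv"))
fp <- read.csv(file.path(in_dir, "fp_breakdown.csv"))

## 1. What drives statistical outcomes? Pearson correlations between each
##    design parameter and the -log10 p-values / significant-taxon counts
##    of the clean datasets.
cl <- oc[oc$contam_level == 0 & is.finite(oc$simpson_p), ]
for (p_col in c("margalef_p", "simpson_p", "bray_p", "binomial_p")) {
  cl[[paste0("nl_", p_col)]] <- neglog10(cl[[p_col]])
}
outcomes <- c(paste0("nl_", c("margalef_p", "simpson_p", "bray_p",
                              "binomial_p")),
              "nsig_nb_wald", "nsig_bias_corrected")
rows <- list()
for (x in c("n_per_group", "n_taxa", "sigma2")) {
  for (y in outcomes) {
    r <- suppressWarnings(correlate(cl, x, y))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = x, outcome = y, r = r$r, p = r$p_value,
      normality_p = r$normality_p, n = r$n)
  }
}
correlations <- do.call(rbind, rows)
write.csv(correlations, file.path(out_dir, "correlations.csv"),
          row.names = FALSE)
cat("Strongest design-parameter correlations (|r| > 0.3):\n")
top <- correlations[abs(correlations$r) > 0.3, ]
print(top[order(-abs(top$r)), ], row.names = FALSE, digits = 3)

## 2. How much contamination does it take to matter? OLS thresholds for a
##    twofold p-value change / a change of two significant taxa.
th <- threshold_table(oc)
write.csv(th, file.path(out_dir, "thresholds.csv"), row.names = FALSE)
cat("\nContaminant thresholds (NA = response does not grow with contamination):\n")
print(th[, c("contam_mode", "response", "n_star")], row.names = FALSE,
      digits = 3)

## 3. Who are the false positives? Category shares and the two-way ANOVA
##    of proportion against DA method and category.
long <- fp_long(fp)
write.csv(long, file.path(out_dir, "fp_long.csv"), row.names = FALSE)
aov_tab <- fp_anova(long)
write.csv(aov_tab, file.path(out_dir, "fp_anova.csv"), row.names = FALSE)
cat("\nTwo-way ANOVA of false-positive proportion (method x category):\n")
print(aov_tab, row.names = FALSE, digits = 3)

pooled <- aggregate(cbind(n_false_positive, n_significant) ~
                      contam_mode + method, data = fp, sum)
pooled$share <- pooled$n_false_positive / pooled$n_significant
write.csv(pooled, file.path(out_dir, "fp_pooled.csv"), row.names = FALSE)
cat("\nFalse-positive share of all significant features, per scenario:\n")
print(pooled, row.names = FALSE, digits = 3)
cat(sprintf("\nWorst scenario: %.1f%% of significant features are false positives.\n",
            100 * max(pooled$share)))
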