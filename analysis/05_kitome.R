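#!/usr/bin/env Rscript
# Stage 5: concordance of genus-level contaminant ("kitome") lists.
#
# Published reagent-contaminant lists are reported at the genus level and
# differ considerably between laboratories. This stage quantifies that
# inconsistency with exact set algebra over a bundled set of SYNTHETIC
# lists (constructed fixtures shaped like published lists -- see
# inst/extdata/kitome_synthetic/README_synthetic.txt), and shows how
# aggressive list-based filtering of a simulated community would be.
#   Rscript analysis/05_kitome.R

library(contamsim)

out_dir <- "results/kitome"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

list_dir <- system.file("extdata", "kitome_synthetic", package = "contamsim")
paths <- list.files(list_dir, pattern = "^kitlist.*\\.txt$", full.names = TRUE)
lists <- read_genus_lists(paths)
st <- overlap_stats(lists)

cat(sprintf("Loaded %d synthetic genus lists (sizes: %s)\n",
            st$n_lists, paste(lengths(lists), collapse = ", ")))
print(st)
cat("Genera by number of lists naming them:\n")
print(st$histogram)

freq <- data.frame(genus = names(st$per_genus_counts),
                   n_lists = unname(st$per_genus_counts))
freq <- freq[order(-freq$n_lists, freq$genus), ]
write.csv(freq, file.path(out_dir, "genus_frequency.csv"), row.names = FALSE)

summary_line <- sprintf(
  "%d lists; union %d genera; %d singletons; %d in exactly two lists; %d in >50%% of lists",
  st$n_lists, st$union_size, st$histogram["1"], st$histogram["2"],
  st$n_majority)
writeLines(summary_line, file.path(out_dir, "summary.txt"))
cat(summary_line, "\n")

# how aggressive is list-based filtering? build a community whose taxon ids
# are genera, half of them drawn from the union of the lists
set.seed(7)
union_genera <- names(st$per_genus_counts)
resident <- c("Lactobacillus", "Gardnerella", "Prevotella", "Sneathia",
              "Ureaplasma", "Finegoldia", "Peptoniphilus", "Anaerococcus",
              "Dialister", "Atopobium")
listed <- sample(union_genera, 10)
genera <- unique(c(resident, listed))
m <- count_matrix(matrix(rpois(length(genera) * 8, 20),
                         nrow = length(genera),
                         dimnames = list(genera, paste0("s", 1:8))),
                  groups = rep(c("S1", "S2"), each = 4))
for (k in c(1, 2, 4)) {
  f <- filter_by_lists(m, lists, k = k)
  cat(sprintf("filtering at k >= %d lists removes %d of %d taxa\n",
              k, attr(f, "n_removed"), nrow(m$counts)))
}
cat("Lower k (more aggressive filtering) can remove genuine residents of\n")
cat("low-biomass communities that happen to appear on reagent lists.\n")
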