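Package: contamsim
Title: Simulation-Based Assessment of Contamination Impact on Microbiome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates factorial grids of two-group synthetic microbiome count
    matrices under a negative-binomial community model with a tunable
    between-group dissimilarity variance, injects simulated contaminant taxa
    under group-balanced (unweighted) or group-biased (weighted) scenarios,
    and evaluates how study design and contamination drive the statistical
    outcomes of standard microbiome analyses: Margalef richness and
    Gini-Simpson alpha diversity with paired t-tests, Bray-Curtis and
    binomial-deviance beta diversity with PERMANOVA, and two per-taxon
    differential-abundance tests (a median-of-ratios-normalised
    negative-binomial Wald test and a compositional bias-corrected log-linear
    test) with Benjamini-Hochberg FDR control. An evaluation layer correlates
    outcomes with design parameters, quantifies contamination impact as
    p-value fold changes and significant-taxon count changes, solves for
    contaminant thresholds, categorises false positives, and summarises the
    concordance of published genus-level contaminant ("kitome") lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
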