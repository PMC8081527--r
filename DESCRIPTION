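Package: crisprigi
Title: Genetic-Interaction Scoring for Paired Pooled CRISPRi Fitness Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide CRISPR interference
    synthetic-defect screens run in two isogenic genetic backgrounds.
    Computes per-guide fitness as control-centred log2 fold-changes of
    normalized sgRNA read counts between paired timepoints, scores per-gene
    genetic interactions as the median difference of guide fitness between
    the mutant and reference screens, and assigns significance with an
    exact minimum-hypergeometric (mHG) test on the ranked guide differences,
    followed by Benjamini-Hochberg false-discovery-rate control and tiered
    hit calling. Includes a seeded generator of synthetic paired screens
    with planted interactions for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
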