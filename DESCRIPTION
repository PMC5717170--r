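Package: ippscore
Title: Iterative Patient Partitioning for Prognostic Gene Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the prognostic value of genes from expression and survival
    data by iterative patient partitioning (IPP): for each gene, patients are
    ordered by expression and every non-overlapping high/low bipartition is
    evaluated with a signed log-rank z-score; the average over all N(N-1)/2
    partitions is the gene's IPP score, so no single expression cutpoint has
    to be chosen. Includes cohort construction from expression and clinical
    tables, breast cancer receptor-subtype stratification, Liptak (weighted
    Stouffer) cross-dataset integration, conventional mean/median-threshold
    log-rank baselines, bootstrap and subsample robustness summaries, null
    score distributions from virtual patient sampling, and a synthetic cohort
    generator with planted proportional-hazards effects for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
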