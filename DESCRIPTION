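Package: dualTCR
Title: Dual TCR Detection and Clonal Expansion Analysis for Single-Cell
    V(D)J Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies single T cells by the number of expressed TCR
    alpha- and beta-chain alleles from single-cell V(D)J contig tables
    (10x Genomics CSV or AIRR Rearrangement TSV), quantifies dual
    TCR-expressing cells and clones across tissue compartments and
    phenotypes, compares clonal expansion between allele classes with
    Welch's heteroscedastic ANOVA and Games-Howell post hoc tests built
    on a studentized-range distribution implementation, and measures how
    much repertoire diversity is underestimated when secondary TCR
    alleles are discarded. Ships a configurable paired-chain repertoire
    simulator with ground-truth labels so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
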