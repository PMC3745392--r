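Package: hapaudit
Title: Quality Control, Reconciliation and Population-Genetic Analysis of
    mtDNA Haplotype Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Audits mitochondrial control-region haplotype datasets against
    the chromatogram evidence behind them. Provides dual-editor consensus
    calling with a one-third inconsistency filter, exact-identity haplotype
    collapse, repository deduplication and support classification against
    re-edited and auxiliary datasets, Nei haplotype and nucleotide diversity
    estimators with variance-based confidence intervals, a chi-square test on
    site-unique haplotype proportions, one-level AMOVA with permutation
    Phi-ST, minimum spanning haplotype networks with two-layer comparison,
    and a seeded synthetic-data generator so every stage is testable without
    access to the underlying sequence archives. Ships the Baltic grey seal
    control-region haplotype distribution tables as worked reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
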