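Package: damidkit
Title: Tissue-Specific DamID Quantification, Enrichment Calling and RNA
    Polymerase DamID Expression Analysis
Version: 0.1.0
Authors@R:
    person("damidkit", "developers", email = "damidkit@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for DamID-seq chromatin profiling:
    GATC-fragment read counting with adapter-anchored filtering,
    pseudocounted relative-read normalization into genome-mean-centered
    log2(fusion/control) tracks at fixed bin sizes or gene level, a
    negative-binomial Wald enrichment test with median-of-ratios size
    factors and trend-shrunk dispersions, chromosome arm/center domain
    statistics, RNA polymerase DamID (RAPID) expressed-gene and
    deregulated-gene calling with a permutation null, gene-set overlap
    reporting, and a seeded synthetic-study generator so the whole
    pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
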