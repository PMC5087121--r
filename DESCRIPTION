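Package: tipchip
Title: Transposon Insertion Profiling by Tiling Microarray (TIP-chip) Analysis
Version: 0.1.0
Authors@R:
    person("TIP-chip", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls ranked transposable-element (TE) insertion candidates from
    tiling-microarray probe intensity tracks using a descending-threshold
    sliding-window peak caller, calibrates per-array peak cutoffs from
    reference-insertion recovery curves (knee detection), merges retained
    peaks across a cell-line panel into insertion loci with
    reference/known-polymorphic/novel-polymorphic/singleton categories,
    tests gene-set over-representation of insertion-bearing genes with an
    exact hypergeometric tail controlled for the array gene universe, and
    associates insertion presence/absence with phenotype profiles by
    point-biserial correlation with Bonferroni correction and cis/trans
    labeling. A synthetic-data module simulates genomes, restriction maps,
    amplicon-footprint probe signals and phenotype matrices so the entire
    pipeline is testable against planted truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
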