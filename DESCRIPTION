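Package: loopscape
Title: Integrative Annotation of Chromatin Loops, TADs, Compartments and
    CTCF Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream integration analyses for chromatin-architecture
    studies: descriptive statistics and four-way loop-TAD arrangement
    classification for HiCCUPS-style loop lists and Arrowhead-style TAD
    calls, A/B compartment assignment of genes by the promoter
    largest-overlap rule with expression comparison, CTCF peak sharing
    between cell types, CTCF-bound loop-anchor classification, methylation
    meta-profiles around peak centers, promoter-contact annotation with
    hypergeometric over-representation analysis, and an expression x Pol II
    x CTCF gene-body cross-analysis.  Includes a seeded synthetic feature
    generator (TADs, loops, peaks, compartments, genes, expression,
    methylation) with a ground-truth ledger for end-to-end validation, and
    a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
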