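Package: cnvensemble
Title: Ensemble Combination, Filtering and Benchmarking of CNV Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for combining copy-number-variant (deletion/duplication)
    call sets produced by heterogeneous whole-genome-sequencing callers.
    Normalizes caller-specific VCF/BED dialects into a common call-set
    representation, applies per-caller quality filters (opposite-type
    "delamp" removal, read-support fractions, adjusted p values,
    same-signal confirmation, non-reference genotype, population allele
    frequency), executes union and intersection-union combination
    strategies built on greedy reciprocal-overlap matching, benchmarks any
    call set against labeled truth pools or reference call sets, annotates
    calls with genomic tracks, and ships a seeded caller simulator with
    configurable error models so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
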