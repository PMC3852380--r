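Package: bindconcord
Title: Integrative Differential Transcription-Factor Binding and Gene
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for contrasting transcription-factor occupancy
    (ChIP-Seq binding regions) and gene expression (RNA-Seq counts)
    between two sample groups. Peak sets from multiple cell lines are
    merged into binding regions, filtered by cross-line support, and
    rescored; binding-region and gene count matrices are tested for
    differential abundance under a negative-binomial model with
    median-of-ratios normalization and a conditioned two-sided exact
    test, with Benjamini-Hochberg correction. Binding regions are
    associated with genes through basal-plus-extension regulatory
    domains, joined with the expression results into gene/region pairs,
    and summarized by a quadrant goodness-of-fit chi-square measuring
    binding-expression concordance, an on/off expression rule, a
    region-based binomial enrichment test, and clustering-ready
    normalized matrices. A seeded synthetic-data generator emulates the
    two-group multi-cell-line study design with planted fold changes
    and a ground-truth ledger for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
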