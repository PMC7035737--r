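Package: trioHeterosis
Title: Trio Transcriptome and Phenotype Heterosis Analysis for Hybrid Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for parent-parent-F1 (trio) heterosis
    experiments in polyploid rice. Implements exact conditional
    negative-binomial differential-expression testing with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    classification of F1-unique tissue-specific differentially expressed
    genes, partitioning of hybrid expression into additive and
    non-additive (mid-parent deviating) components, mid-parent and
    high-parent heterosis statistics with significance tests, mapping of
    gene sets onto QTL interval catalogues, keyword-based functional
    categorization with hypergeometric enrichment, and 2^-ddCt qPCR
    relative quantification. Ships a synthetic trio-experiment generator
    with planted truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    limma,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
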