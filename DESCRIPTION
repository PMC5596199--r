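Package: regulocate
Title: Regulatory Motif Co-Localization Analysis for Bacterial RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline connecting bacterial mutant transcriptomes to
    candidate regulatory motifs: FPKM normalization and t-test differential
    expression with minimum-count gating and Benjamini-Hochberg FDR,
    complete-linkage clustering of log2 fold-change profiles, ZOOPS EM de novo
    motif discovery with QFAST E-values, position-weight-matrix scanning with
    exact p-values, genome-wide motif kernel-density tracks co-localized with
    expression effect size, operon-position signal-decay statistics
    (ANOVA/Tukey HSD), and regulator-gene region enrichment. Includes a seeded
    synthetic-data generator (multi-replicon genomes, operon-structured
    annotations, planted palindromic motifs, negative-binomial counts) so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
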