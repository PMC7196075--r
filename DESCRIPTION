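Package: hecscreen
Title: UMI Quantification, Scoring and Signature Screening for Hemogenic
    Endothelium Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested reimplementation of the computational pipeline used to
    identify HSC-primed hemogenic endothelial cells from STRT-style
    single-cell UMI transcriptomes: barcode demultiplexing and UMI
    deduplication from paired FASTQ, cell and gene quality filters with
    log2(TPM/10 + 1) normalization, highly-variable-gene selection and
    graph-based clustering, bipolar arteriovenous scoring and rule-based
    cell-cycle phase classification, dual-method (Wilcoxon + ROC)
    differential-expression calling, the multi-stage hemogenic-endothelium
    signature-gene screen, multi-cluster expression-pattern assignment by
    consensus k-means with correlation reassignment, and Fisher regulon
    overlap testing. A synthetic-data generator with full ground truth
    stands in for the deposited embryo dataset and drives the test suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    zoo,
    stats,
    utils,
    tools,
    methods
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
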