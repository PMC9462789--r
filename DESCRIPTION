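Package: crescan
Title: Sequence Analysis and Modelling of Cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated toolkit for the analysis and modelling of
    cis-regulatory element (CRE) DNA sequences. Provides tidy containers and
    input/output for sequences (FASTA, 2bit), genomic regions (GFF, GTF, BED,
    coordinate lists) and genome-wide signal curves (Wiggle); generative
    background models (i.i.d. and nth-order Markov chains); composable,
    trainable DNA feature sets (motif and motif-pair occurrence frequencies,
    k-spectrum and k-spectrum mismatch kernels); sequence models with
    sliding-window scoring, precision-targeted threshold calibration and
    genome-wide prediction, including a log-odds motif-pair scorer and
    convolutional network architectures with exact trainable-parameter
    accounting; and a cross-validation workbench for imbalanced multi-class
    data with ROC/PR curves and t-based confidence intervals. A
    synthetic-genome generator with planted CREs makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils,
    withr,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    pROC,
    e1071,
    randomForest
Config/testthat/edition: 3
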