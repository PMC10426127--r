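Package: scregmotif
Title: De Novo Regulatory Motif Discovery and Cell-Type Influence Scores
    from Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers regulatory sequence motifs de novo and quantifies
    their per-cell-type influence on gene expression or chromatin
    accessibility from single-cell data. A shallow convolutional network
    (convolution, exponential linear unit, global max pooling, linear
    readout) is trained to regress kNN-pooled single-cell profiles on
    one-hot encoded promoter or peak sequences. Convolutional filters are
    converted to position frequency matrices from their max-activating
    subsequences, aligned to a motif database, and scored per pool and
    cell type by leave-one-out ablation. Includes kNN pooling with
    geometric-sketch seed selection, nested cross-validation with
    successive-halving hyperparameter search, MEME-format motif I/O,
    transcription-factor and gene-set association analyses, and a fully
    specified synthetic-data generator with planted motifs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
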