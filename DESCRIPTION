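Package: densebind
Title: DenseNet Classifiers and Base-Resolution Interpretation of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcription factor binding site (TFBS) classification
    datasets from peak intervals, trains a DenseNet-style one-dimensional
    convolutional classifier on one-hot encoded DNA, and localizes
    base-resolution core motifs in any input sequence by combining
    reference-based contribution scores (integrated gradients against
    dinucleotide-shuffled references), in-silico tiling deletion, in-silico
    saturation mutagenesis, and global importance analysis. Also provides
    position weight matrix scanning with exact p-value calibrated thresholds,
    MEME-style aggregation scoring baselines, a motif co-occurrence statistic,
    evaluation metrics (ROC-AUC, PPV, NPV, recall), and a synthetic
    planted-motif benchmark generator so the whole pipeline is testable
    without external data. The neural network engine (convolution,
    batch normalization, dense connectivity, Adam, backpropagation including
    input gradients) is implemented in R on top of BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
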