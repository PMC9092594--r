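Package: acpmka
Title: Anticancer Peptide Classification with Multi-Kernel Convolution and Self-Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of anticancer peptides (ACPs) from their
    amino-acid sequence. Implements a sequence model that combines a learnable
    residue embedding, parallel same-length convolutions with several odd kernel
    widths fused by a linear projection, sinusoidal positional encoding, stacked
    multi-head self-attention encoder blocks and a focal-loss-trained
    classification head, together with the full evaluation harness: confusion
    metrics (sensitivity, specificity, precision, accuracy, MCC, F1, correct
    index), ROC/PR areas, stratified k-fold cross-validation, learning-rate and
    kernel-combination sweeps, architecture ablations, and PCA/t-SNE
    visualization of penultimate-layer features across training. A synthetic
    peptide generator with a plantable sequence motif makes every stage testable
    without external benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
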