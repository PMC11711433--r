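Package: tokenmixer
Title: Hybrid Convolutional-Transformer Models for Histopathology Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the TokenMixer hybrid convolutional-transformer
    architecture and its three comparators (a compact vision transformer,
    TokenLearner, and ConvMixer) for benign/malignant and eight-way tumor
    subtype classification of magnification-stratified histopathology
    images. Ships a self-contained reverse-mode automatic differentiation
    engine with dense, convolutional, attention and normalization layers;
    exact trainable-parameter auditing; a BreakHis-style image reader with
    stratified splitting and on-the-fly augmentation; a seeded synthetic
    histology image generator for end-to-end testing; a training and
    threefold cross-validation harness; and a classification metric suite
    (accuracy, precision, sensitivity, specificity, F1, ROC-AUC, MCC,
    Cohen's kappa, G-mean).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
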