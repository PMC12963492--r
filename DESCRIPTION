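Package: lsetnet
Title: Lightweight Squeeze-and-Excitation Transformer Networks for Leaf
    Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements LSeTNet, a lightweight hybrid convolutional /
    squeeze-and-excitation / transformer classifier for medicinal-plant
    leaf disease images, together with its full experimental scaffolding:
    contrast-enhancing preprocessing (CLAHE on the LAB L-channel, Gaussian
    denoising, unsharp masking, train-only channel standardization),
    leakage-free stratified splitting before quota-based augmentation,
    cross-validated training with Adam and early stopping, evaluation
    (confusion matrices, per-class and macro metrics, one-vs-rest ROC/AUC),
    explainability (Grad-CAM, LIME superpixel surrogates, t-SNE projections
    with cluster statistics), and statistical model comparison (paired t,
    McNemar, Friedman with Nemenyi post-hoc). A deterministic procedural
    generator of twelve-class synthetic leaf imagery makes every pipeline
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    yaml,
    cluster,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    class,
    optparse
Config/testthat/edition: 3
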