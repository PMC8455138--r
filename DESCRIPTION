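Package: ethoflow
Title: Frame-Wise Behavior Classification from Video with Two-Stream Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised, frame-wise, multi-label classification of animal
    behavior directly from video pixels. Implements the full pipeline: an
    unsupervised optic-flow generator trained with reconstruction losses
    (Charbonnier pixel error, structural similarity, flow smoothness and
    sparsity), a two-stream convolutional feature extractor trained with a
    class-imbalance-aware focal loss and L2-SP regularization, a temporal
    Gaussian-mixture sequence model over saved per-frame features, and
    ethogram postprocessing (per-class threshold optimization, bout-length
    filtering, background complement) with bout statistics, transition
    matrices and shuffle-based chance levels. Includes a synthetic
    behavior-video generator with controllable semi-Markov bout structure
    and class imbalance, and a keypoint-based comparison classifier. All
    networks run on a small built-in reverse-mode automatic differentiation
    engine with compiled convolution kernels, so the package has no deep
    learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    yaml,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
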