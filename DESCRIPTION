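Package: mpunet
Title: Multi-Path U-Net Segmentation for Cell and Colony-Forming-Unit Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a multi-path U-Net for semantic
    segmentation of microscopy and agar-plate images. Each receptive-field
    pathway is an independent encoder-decoder with its own pooling window;
    pathways are merged at the bottleneck by channel concatenation followed by
    cross-channel layer normalization and spatial (channel-wise) dropout. The
    package includes the Tversky plus cross-entropy training objective, Dice
    evaluation, five-fold cross-validation with early stopping, preprocessing
    (Gaussian-smoothed rescale and per-image z-scoring), colony-forming-unit
    counting with interval binning, and a deterministic synthetic plate/cell
    scene generator with exact ground-truth masks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
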