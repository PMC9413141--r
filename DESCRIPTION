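Package: lcanet
Title: Local and Context-Attention Network for Ultrasound Nodule Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates an encoder-decoder segmentation network for
    low-contrast nodules in ultrasound images. The network combines three
    bespoke blocks: a windowed context-attention block in which 8x8 query
    windows attend to overlapping 10x10 key-value windows with a learned
    relative position bias; a residual backbone block built from factorized
    7x1 and 1x7 convolutions with the Mish activation; and a nodule-adaptive
    convolution block that mixes four dilated-convolution branches (receptive
    fields 1, 5, 7 and 11) with input-conditioned simplex weights. Includes a
    class-imbalance pixel loss, the standard confusion-matrix segmentation
    metrics, a reproducible training loop (AdaBound, Adam or SGD with cosine
    annealing and stochastic augmentation), an ablation driver, and a
    synthetic ultrasound-phantom generator with exact ground-truth masks.
    Network forward and backward passes are implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
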