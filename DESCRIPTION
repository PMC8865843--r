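Package: hapticAE
Title: Unsupervised Efficient Coding of Vibrotactile Texture Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how a compressed, unsupervised representation of
    vibratory texture signals relates to haptic material perception. The
    package simulates accelerometer recordings of tool-mediated texture
    exploration together with perceptual rating tables, band-pass filters and
    segments the traces into short windows, trains a 1-D convolutional
    autoencoder with a parameterisable bottleneck on the normalized windows,
    and analyses the learned latent space: principal-component projection,
    per-material embeddings, category centroid distance matrices and their
    correlation with rating-derived perceptual distances, leave-one-material-
    per-category-out linear classification with a label-shuffling bootstrap
    null, and temporal-frequency tuning of the latent dimensions probed with
    a sinusoid bank and compared against canonical tactile-afferent tuning
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
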