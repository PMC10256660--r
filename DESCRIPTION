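Package: stvnet
Title: Shape-Prior-Constrained V-Net Segmentation with a Spatial
    Transformer Module
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Volumetric segmentation of CT-like images with a 3D V-Net
    encoder-decoder coupled to a spatial transformer module that aligns a
    morphologically generated shape prior to the network prediction.
    Implements the compound Dice/L2 objective, a three-stage training
    schedule with dynamically updated shape priors, depth-wise
    sliding-window inference with Otsu binarization, overlap and surface
    evaluation metrics (Dice, sensitivity, specificity, Hausdorff and
    average surface distance in millimetres), Fourier slice-thickness
    resampling, and a synthetic femur-like phantom generator so the whole
    pipeline is exercisable without clinical data. The 3D convolutional
    layers and the trilinear resampler with analytic gradients are
    implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
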