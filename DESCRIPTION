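Package: faunet
Title: Frame-Attention Convolutional Transformer U-Net for Fluorescence
    Microscopy Denoising
Version: 0.1.0
Authors@R:
    person("faunet", "maintainers", email = "faunet@example.org",
           role = c("aut", "cre"))
Description: Supervised denoising of fluorescence microscopy stacks with a
    convolutional transformer U-net whose attention operates across the
    frame (Z or T) axis.  Key, query and value maps are produced by 2D
    convolutions, attention scores are pooled over space so the cost is
    linear in pixel count, and a long skip connection makes the untrained
    network the identity.  Ships a two-stage training scheme (backbone
    pretraining on pooled data, few-pair fine-tuning for a new experiment),
    tiled feather-blended inference, PSNR and volumetric SSIM metrics, a
    synthetic phantom and Poisson-Gaussian noise simulator including
    repetition-average series, multi-page TIFF and manifest I/O, and a
    command-line interface.  The full training engine (forward, backward,
    Adam) is implemented in R with Rcpp/Armadillo convolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
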