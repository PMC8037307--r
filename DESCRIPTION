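Package: sacnet
Title: Self-Supervised Susceptibility-Artifact Correction for Reversed
    Phase-Encoding EPI
Version: 0.1.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Corrects susceptibility-induced geometric distortion in pairs of
    3D echo-planar images acquired with reversed phase-encoding directions.
    A 3D convolutional encoder-decoder maps the image pair to a full 3D
    voxel-displacement field; the two images are resampled along +U and -U by
    a differentiable trilinear spatial transform, and the network is trained
    without ground truth by an image-pair similarity loss (local normalized
    cross-correlation, local cross-correlation, or mean squared error), a
    diffusion smoothness penalty on the field, and an optional anatomical
    regularizer based on normalized mutual information against a co-registered
    T1-weighted volume that is needed only at training time. Includes a
    synthetic phantom and distortion simulator for desk-scale validation,
    evaluation metrics, NIfTI input/output, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
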