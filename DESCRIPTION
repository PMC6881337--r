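Package: dectdnc
Title: Physics-Informed Deep Non-Contrast Image Synthesis from Dual-Energy CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesising non-contrast head CT images from
    dual-energy CT (DECT) acquisitions. The package builds a physics-informed
    two-dimensional lookup table mapping (low-energy, high-energy) Hounsfield
    unit pairs to virtual non-contrast (VNC) intensities, imputes unobserved
    lookup cells with a DCT-based penalized-least-squares inpainter, and
    trains a dilated residual convolutional network to predict the residual
    between true non-contrast images and the lookup VNC, composing "deep
    non-contrast" (DNC) images. Includes a synthetic DECT brain-phantom
    generator (tissue classes, iodine enhancement with a configurable
    low/high energy ratio, energy-dependent noise), a linear three-material
    decomposition stand-in for vendor VNC software, brain-mask morphology,
    and brain-masked evaluation metrics (batched RMSE and Spearman rank
    correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
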