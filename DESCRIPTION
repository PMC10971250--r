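Package: mrisr
Title: Residual-Learning Super-Resolution for MRI-Like Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for single-image super-resolution of
    single-channel medical image slices with a 20-layer residual
    convolutional network (VDSR-style). Provides synthetic MRI phantom
    generation with Rician noise and embedded fiducial targets, DICOM/PNG/JPEG
    slice I/O with 8-bit normalisation, construction of bicubically degraded
    residual training pairs on the luminance channel, SGDM training with
    gradient clipping and a stepped learning-rate schedule, full-image
    residual reconstruction, PSNR/SSIM quality metrics (global and windowed),
    and a paired evaluation design comparing super-resolution against bicubic
    interpolation across scale factors 2, 3 and 4, including sub-pixel
    fiducial coordinate-invariance checks for stereotactic targeting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jpeg,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
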