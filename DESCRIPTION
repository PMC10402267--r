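Package: flashigrt
Title: Image-Guided Volumetric Reconstruction and Water-Equivalent-Thickness
    Evaluation for Proton FLASH Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deep-learning image guidance in proton FLASH
    radiotherapy at desk scale: a seeded 4D breathing-thorax phantom
    generator, a Siddon ray-traced digitally-reconstructed-radiograph
    projector producing orthogonal kV projection pairs, a 2D-to-3D residual
    encoder-decoder network trained with a composite mean-absolute-error plus
    gradient loss under leave-phase-out cross-validation, image-quality
    metrics (ME, MAE, PSNR, SSIM, CT-number histograms), and a ray-traced
    water-equivalent-thickness module with HU-to-relative-stopping-power
    conversion and Gaussian histogram fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    minpack.lm,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
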