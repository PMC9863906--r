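Package: tumorgan
Title: Adversarial 3D Segmentation of Brain Tumours from Multimodal MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric conditional adversarial network for brain tumour
    segmentation from co-registered multimodal MRI (T1, T1gd, T2, FLAIR).
    Provides a self-contained 3D network engine (strided and transposed
    convolutions, instance normalisation, residual blocks, Adam) built on
    compiled primitives, an encoder-decoder generator paired with a patch
    discriminator trained with a composite objective (mean-absolute
    adversarial terms plus a weighted generalized dice loss), a seeded
    simulator of BraTS-like multimodal phantoms with nested four-class
    tumour geometry, NIfTI preprocessing (z-score intensity normalisation,
    patch extraction and augmentation), sliding-window prediction with
    overlap averaging, and per-case DSC/PSNR/SSIM evaluation with cohort
    aggregation. A command-line entry point wires the stages into an
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
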