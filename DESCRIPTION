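Package: dualsct
Title: Dual-Input CBCT and MRI Synthetic-CT Generation with Proton-Range
    Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for conditional-GAN synthesis of CT volumes from cone-beam
    CT (CBCT) with an optional coregistered T1-weighted MRI channel, aimed at
    adaptive proton therapy workflows for the head. Includes a seed-reproducible
    multimodal digital head-phantom simulator (aligned CT/CBCT/MRI triplets with
    organ labels), NIfTI volume I/O and preprocessing (rigid resampling, HU
    clipping, min-max normalization, patient-level splits, axial slice
    batching), ResUnet and SwinUnet generators with a patch discriminator built
    on a lightweight reverse-mode autodiff engine, Pix2Pix and CycleGAN training
    regimes with generator pre-training and asymmetric learning rates, masked
    image-quality and delineation metrics (MAE, PSNR, SSIM, Dice, Hausdorff),
    HU-to-stopping-power conversion, a straight-ray water-equivalent-path-length
    proton range engine with distal-R80 maps and difference histograms, and
    dose-volume histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
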