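Package: longsynth
Title: Longitudinal MR Image Prediction with Multi-Contrast Perceptual
    Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts a subject's structural brain MR image at a missing
    longitudinal timepoint from the image at another timepoint, using 3D
    U-Net generators trained with a composite adversarial, voxel-wise
    reconstruction (L1), and perceptual objective.  Supports single-contrast
    (PGAN) and multi-contrast shared-encoder dual-decoder (MPGAN) generators
    for joint T1w/T2w prediction, a deterministic synthetic longitudinal
    brain-phantom simulator with ground-truth tissue labels for download-free
    experimentation, segmentation-agreement evaluation metrics (relative
    absolute volume difference, average symmetric surface distance, Dice,
    Tanimoto error, and a reference-scaled fused score), and an end-to-end
    simulate/train/impute/evaluate pipeline.  All networks and the training
    loop are implemented natively (with compiled kernels) so the package has
    no deep-learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
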