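Package: petseg
Title: Adaptive Patch-Sampled 3D Lesion Segmentation and Quantification
    for PSMA PET-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for training and evaluating voxel-wise 3D classifiers
    that detect prostate tumour/recurrence, lymph-node metastases and bone
    metastases in whole-body PSMA PET-CT. Implements loss-adaptive patch
    sampling with per-voxel sample masks, weighted categorical
    cross-entropy training of a compact 3D U-Net, sliding-window
    whole-volume inference, lesion-level sensitivity/PPV evaluation by
    segmentation overlap, and tumour-burden quantification as total lesion
    volume (TLV) and total lesion uptake (TLU). A synthetic PET-CT phantom
    generator with simulated alternative readings makes the whole pipeline
    testable without clinical data.
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
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
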