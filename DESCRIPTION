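Package: lcseg
Title: Ensemble 3D U-Net Segmentation and MRI Feature Extraction for the
    Locus Coeruleus
Version: 0.1.0
Authors@R: person("LC Imaging", "Tools", email = "lcseg@example.org",
    role = c("aut", "cre"))
Description: A fully automatic analysis pipeline for the locus coeruleus
    (LC) on neuromelanin-sensitive FLASH-like MRI volumes: a two-stage
    cascade of tiny 3D U-Nets (whole-volume localization followed by
    patch-wise segmentation) with five-member ensembling (probability
    averaging for localization, per-voxel majority vote for
    segmentation), an LC-oriented orthonormal coordinate frame derived
    from per-hemisphere principal axes, offset-based automatic
    reference-region placement in the pontine tegmentum, and extraction
    of the standard LC MRI biomarkers (maximum and median contrast
    ratios, subregional contrast ratios, signal length and volume).
    Includes NIfTI input/output, Fourier (sinc) upsampling, a synthetic
    brainstem phantom generator with ground-truth masks for end-to-end
    validation, subject-level cross-validation fold machinery, and
    evaluation metrics (Dice similarity coefficient, sensitivity /
    specificity, probabilistic templates, Cohen's d).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
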