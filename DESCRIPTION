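Package: prostacad
Title: Cascaded Detection and Localization of Clinically Significant
    Prostate Cancer on Biparametric MRI
Version: 0.1.0
Authors@R:
    person("prostacad", "developers", email = "prostacad@example.org",
           role = c("aut", "cre"))
Description: A fully automated pipeline for detecting and localizing
    clinically significant prostate cancer (csPCa) on biparametric
    prostate MRI (ADC map plus T2-weighted imaging).  Implements the
    complete chain: a synthetic phantom generator producing biparametric
    cohorts with ground-truth anatomy, preprocessing (rigid header-based
    registration, K-means prostate localization, cropping,
    normalization, augmentation), a cascaded residual U-Net
    (gland -> peripheral zone -> lesion) trained with Adam and a soft
    Dice loss, lesion/sextant/patient-level evaluation with exact
    Clopper-Pearson confidence intervals and McNemar paired tests, and
    machine-readable structured reports with sextant localization and
    key images.  Volumes are read and written as NIfTI-1; DICOM series
    are read.  No GPU or external deep-learning runtime is required:
    the network forward/backward passes are implemented in compiled
    code inside the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
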