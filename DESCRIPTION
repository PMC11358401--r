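Package: hemilabel
Title: Whole-Brain Training Label Maps from Single-Hemisphere MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds whole-brain training label maps from single-hemisphere
    ex vivo brain MRI and manual hypothalamus subregion labels. Provides
    NIfTI-based volume handling (canonical RAS reorientation, left-right
    flipping, isotropic resampling), background masking and bias-field
    correction, unsupervised k-means context labeling, fusion of manual and
    context labels with morphological closing, cost-optimized hemisphere
    mirroring across the mid-sagittal plane, synthetic MRI generation from
    label maps via per-label Gaussian intensity models with geometric
    augmentation and resolution simulation, and segmentation agreement
    metrics (Dice coefficient, average Hausdorff distance). A deterministic
    phantom generator supplies hemisphere-like test volumes so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
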