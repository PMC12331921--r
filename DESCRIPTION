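Package: gliomctv
Title: Progression-Guided Clinical Target Volumes for Glioblastoma Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining radiotherapy clinical target volumes (CTVs)
    in glioblastoma from pre-radiotherapy multi-parametric MRI. Implements
    voxel-wise transition labelling between pre-treatment and progression
    scans, per-patient median statistics and paired Wilcoxon comparisons,
    patient-stratified random-forest progression classifiers, a 3D U-Net
    trained with size-adaptive Tversky ("Progression Coverage Coefficient",
    PCC) losses, geometric RTOG / EORTC comparison CTVs, and a full
    segmentation evaluation suite (sensitivity, specificity, Dice, 95th
    percentile Hausdorff distance, Tversky, PCC). Ships a seeded synthetic
    cohort generator emulating aligned pre-RT/progression case pairs so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
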