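Package: localradiomics
Title: Local Radiomics for Detecting Radioresistant Tumor Sub-Volumes on CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for local (sub-volume) radiomics analysis of planning CT
    images of solid tumors. Provides NIfTI image and ROI handling, isotropic
    resampling and Hounsfield-unit windowing, a fixed vocabulary of 161
    intensity and texture features (GLCM, GLRLM, GLSZM, GLDZM, NGTDM, NGLDM)
    computed on masked regions, two sub-volume partitioning schemes of a gross
    tumor volume (fixed-count octants and a fixed-size shifted grid),
    recurrence labeling of sub-volumes, and a feature-selection plus logistic
    classification cascade (voxel-count correlation filter, PCA with parallel
    analysis, Spearman grouping, per-group AUC representatives, backward-AIC
    logistic regression, stratified bootstrap confidence intervals, and
    patient-level leave-one-out cross-validation). A synthetic phantom and
    cohort generator with known recurrent sub-volumes supports end-to-end
    testing without patient imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
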