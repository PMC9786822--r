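Package: strokeradiomics
Title: Radiomics Prognosis Pipeline for Follow-Up MRI in Acute Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a follow-up-MRI radiomics prognosis
    analysis for acute ischemic stroke. From paired DWI and T2-FLAIR lesion
    volumes it computes 107 radiomic features per modality (first-order, 3D
    shape, and GLCM/GLRLM/GLSZM/NGTDM/GLDM texture families), combines them
    with clinical covariates, and trains gradient-boosted tree classifiers for
    the binary 90-day modified Rankin Scale outcome under nested stratified
    cross-validation with SHAP-based feature selection. Models built on five
    feature sets are compared with DeLong's test for correlated ROC curves.
    Because the trial data are not public, a seeded synthetic-cohort module
    generates lesion images, masks, clinical covariates and outcomes with the
    statistical structure the analysis assumes, so that every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    xgboost,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
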