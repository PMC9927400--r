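Package: rfaradiomics
Title: Multimodal Radiomics and Clinical Fusion Modelling of Thermal Ablation Response
Version: 0.1.0
Authors@R: person("RFA", "Radiomics Team", role = c("aut", "cre"), email = "maintainer@example.org")
Description: End-to-end pipeline for predicting immediate complete response of
    CT-guided radiofrequency ablation of lung metastases from paired pre- and
    post-ablation CT volumes and clinical covariates. Provides a synthetic
    phantom-plus-cohort generator, isotropic B-spline resampling and HU
    windowing, native IBSI-style texture features (GLCM, GLRLM, GLDM, GLSZM,
    NGTDM, first-order, shape), five-criterion minimum-redundancy
    maximum-relevance feature selection with frequency consensus,
    Gaussian-mixture cluster-stratified data division, SMOTE-balanced random
    forest clinical and radiomics models, and decision-level weighted fusion
    evaluated by ROC/AUC with the DeLong test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
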