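Package: ggnrad
Title: Radiomic Prediction of Invasiveness for Pure Ground-Glass Lung Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end CT radiomics for pure ground-glass lung nodules
    (pGGNs): synthetic 3D phantom generation with ground-truth masks,
    isotropic resampling and volume-of-interest extraction, semi-automatic
    hybrid level-set segmentation with Frangi-vesselness vessel removal, a
    deterministic 404-feature radiomic registry (morphology, histogram,
    GLCM, GLRLM, GLSZM), and a statistical core that screens features with
    two-sample t-tests, z-scores them, runs sequential forward selection
    into a logistic model, and evaluates it with leave-one-out
    cross-validation, ROC/AUC and a Youden-index cutoff, including frozen
    application to an external cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
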