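Package: radphen
Title: Radiomic Phenotyping of Tumor CT with Nested ComBat Harmonization and Prognostic Survival Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for CT radiomic biomarker discovery in
    oncology cohorts: resampling of image/mask pairs to the cohort-minimum
    voxel spacing, extraction of a 102-feature radiomic descriptor set across
    eight families (intensity, histogram, intensity-volume-histogram,
    morphology, GLRLM, GLSZM, NGTDM, LBP), empirical-Bayes ComBat
    harmonization of multi-batch acquisition effects with protected clinical
    covariates and nested permutation selection scored by the k-sample
    Anderson-Darling test, phenotype discovery by Ward hierarchical
    clustering with consensus-clustering stability and SigClust significance
    assessment, and cross-validated Cox proportional-hazards prognostic
    modeling of progression-free survival with Kaplan-Meier median-risk
    stratification. Includes a synthetic-cohort generator (feature tables
    with planted batch/cluster/covariate structure, proportional-hazards
    outcomes, and textured ellipsoid image fixtures) so the full pipeline is
    testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    randomForest,
    igraph,
    RNifti,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
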