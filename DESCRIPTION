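Package: hemorisk
Title: Multiparametric MRI Prediction of Parenchymal Hemorrhage After
    Stroke Reperfusion Therapy
Version: 0.1.0
Authors@R: person("hemorisk", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Voxelwise dynamic susceptibility contrast (DSC) perfusion
    modelling for acute ischemic stroke: conversion of T2*-weighted signal
    to concentration-time curves, two-regressor leakage (K2) fitting
    against a contralateral normal-appearing white-matter reference,
    leakage-corrected contralateral-normalized CBV, and truncated-SVD Tmax
    maps; lesion volume-of-interest extraction with percentile feature
    computation (10th percentile CBV and ADC, 90th percentile K2); and two
    predictive models of parenchymal hemorrhage after reperfusion therapy -
    a fixed-coefficient logistic score and a two-threshold classification
    tree - together with their fitting procedures (backward-stepwise
    logistic regression by IRLS, binary recursive partitioning), ROC and
    balanced-accuracy metrics, and a synthetic-cohort generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
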