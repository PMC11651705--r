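Package: acropred
Title: Biomarker-Guided Treatment Assignment and Trial Simulation for Acromegaly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a personalized treatment-decision algorithm for
    acromegaly that assigns first-line medical therapy (first-generation
    somatostatin receptor ligands, pegvisomant, or their combination) from
    predictive biomarkers: the short acute octreotide test, T2-weighted MRI
    tumor signal intensity, cavernous sinus invasion, and tumor E-cadherin
    immunoexpression. Includes growth-hormone assay harmonization by affine
    calibration to a reference immunoassay, IGF-1 standard-deviation scores
    against a pluggable age/sex reference, ellipsoid tumor volumetry, a
    dose-titration state machine on a 3-month visit grid, a synthetic cohort
    generator emulating a two-arm trial population, and the endpoint analysis
    pipeline: control proportions with Fisher's exact test, Kaplan-Meier
    time-to-control, age- and sex-adjusted Cox hazard ratios, rank-based ROC
    AUC with bootstrap intervals, Spearman correlation matrices,
    counterfactual evaluation of the decision rule on a standard-therapy arm,
    and two-proportion sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
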