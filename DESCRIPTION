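Package: anomiaPLS
Title: Prognostic Modelling of Anomia Treatment Response from Lesion Load
    and Therapy Dose
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and stress-testing prognostic models of
    individual response to computerised anomia therapy after left-hemisphere
    stroke. Binary lesion masks are encoded as per-region lesion-load
    fractions against a (possibly multi-atlas, overlapping) region set;
    partial least squares (PLS) regression models over configurable
    predictor blocks (demographics, initial naming severity, therapy hours,
    behavioural scores, lesion loads) are compared against a group-mean null
    model under repeated k-fold cross-validation with fold plans shared
    across models; paired model comparison uses the Wilcoxon signed-rank
    statistic thresholded by a within-pair sign-flip permutation null with
    familywise error control; fitted models are interpreted by a
    data-perturbation procedure that correlates shuffled predictor values
    with model predictions. A synthetic-cohort generator reproduces the
    statistical structure the analysis assumes (contiguous lesion blobs in a
    restricted territory, correlated region loads, a planted region-weight
    map plus a therapy-hours term), so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
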