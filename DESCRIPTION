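Package: mciTrajectory
Title: Individualized Trajectory Forecasting for Mild Cognitive Impairment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models individualized progression trajectories in amnestic mild
    cognitive impairment from irregular longitudinal clinical data. Visit-level
    MRI markers, neuropsychological scores, APOE genotype and amyloid burden
    are fused by a feature-level self-attention module, propagated through a
    gated recurrent unit modified with a temporal decay factor and an
    observation-mask vector, and mapped by multi-task linear heads to
    next-visit predictions of six MRI markers and nine cognitive scores.
    Includes decay-weighted imputation for missing visits, a synthetic
    amyloid-stratified cohort simulator, a stratified cross-validation and
    grid-search training harness with early stopping, forecast metrics with a
    paired exact Wilcoxon test, downstream amyloid-positivity classification
    scenarios, and relative-change / attention-weight trajectory analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Regression, Classification
RoxygenNote: 7.3.3
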