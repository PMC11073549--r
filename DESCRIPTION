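Package: edgets
Title: Task-Dependent Functional Correlations from Edge Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of intrinsic and task-dependent functional
    correlations from edge (cofluctuation) time series of parcellated BOLD
    signals. Implements the full mass-univariate pipeline: design-matrix
    construction (double-gamma HRF triplets, FIR task basis, discrete-cosine
    drift, expanded motion parameters), ordinary least squares with AR(1)
    prewhitening, node-level activation GLMs, edge-level cofluctuation GLMs,
    a generalized psychophysiological interaction (gPPI) comparator,
    group-level inference with Holm-Bonferroni and Benjamini-Hochberg
    correction, and a battery of between-task similarity analyses (Spearman,
    Dice, edge subsampling, region-wise profiles, subject-level beta-map
    similarity, Mantel tests with subsampled confidence intervals, SNR
    filtering). Includes a synthetic multi-subject block-design BOLD cohort
    generator with modular intrinsic covariance, condition-dependent
    covariance modulation, HRF-convolved evoked responses, AR(1) noise and
    nuisance confounds, providing ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'regressors.R'
    'glm-core.R'
    'edge-dynamics.R'
    'subject-pipelines.R'
    'cohort-analysis.R'
    'group-stats.R'
    'similarity.R'
    'synthetic-data.R'
    'io.R'
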