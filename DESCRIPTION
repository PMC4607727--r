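Package: bayestraj
Title: Bayesian Mixed-Effects Modelling of Longitudinal Structural Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian mixed-effects models for longitudinal
    structural trajectories, as used in longitudinal voxel-based morphometry.
    Subject-specific polynomial trajectories of age are embedded in a two-level
    linear Gaussian model whose covariance components (measurement noise and
    between-subject variability of each trajectory coefficient, per group) are
    estimated by Expectation Maximization with a Fisher-scoring update on
    log-variance hyperparameters. The exact Gaussian E-step yields the joint
    posterior over individual and group trajectory parameters; the variational
    free energy equals the log model evidence and supports Bayes-factor
    comparison of trajectory models of different polynomial degree. Inference
    uses posterior probability maps (exceedance probabilities of parameter
    contrasts). Includes a synthetic-data suite (trajectory ensembles,
    balanced/unbalanced and sparse acquisition designs, generalized-normal
    errors with controlled skewness and kurtosis, summary-statistic
    comparator, empirical false-positive-rate calibration) and a
    mass-univariate voxelwise runner over NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    parallel,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
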