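Package: covertnf
Title: Simulation and Analysis of Covert Connectivity-Based fMRI Neurofeedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing covert, connectivity-based
    real-time fMRI neurofeedback experiments. Provides a seeded synthetic
    cohort generator for three-region-of-interest BOLD-like time series and
    small voxel grids with programmable day-by-day connectivity trajectories;
    a streaming two-point trend-agreement feedback decision engine with
    score/board bookkeeping and k-point sliding-window generalisations;
    offline connectivity metrics (pairwise Pearson correlations, Fisher z,
    a composite target-target minus target-control difference measure) and
    validation of the two-point proxy against offline correlation; day-level
    learning statistics with paired sign-flip permutation inference, subset
    robustness enumeration, Welch group-interaction tests and retention
    analysis; voxelwise differential-correlation change maps with
    across-subject t-tests and multi-threshold cluster-size permutation
    correction; and brain-behaviour correlation analyses with a 3-SD outlier
    rule and partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
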