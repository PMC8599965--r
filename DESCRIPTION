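Package: dynconn
Title: Dynamic Brain-State, Complexity and Connectome Topology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the temporal dynamics of large-scale brain
    networks from component timecourses. Fits a group-level multivariate
    Gaussian hidden Markov model with a shared covariance matrix and derives
    fractional occupancy, switching rate and state lifetimes; computes
    multiscale sample entropy; builds wavelet-correlation functional
    connectomes with density thresholding and degree-preserving null-model
    normalization of clustering and path length; and provides permutation-based
    group statistics (Freedman-Lane GLM with max-statistic family-wise error
    correction, Kaiser-criterion PCA of occupancy, partial correlations,
    moderation tests, Steiger's Z). Includes motion quality-control metrics
    with a 1-SD exclusion rule, a synthetic two-group cohort generator with
    planted state-occupancy effects for validation, and an end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
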