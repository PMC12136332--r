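Package: dwgnn
Title: Dynamically Weighted Graph Neural Networks for Dynamic Functional
    Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies early mild cognitive impairment (eMCI) versus normal
    controls from ROI-level resting-state BOLD time series. Builds low- and
    high-order dynamic functional connectivity networks by sliding-window
    Pearson correlation, sparsifies edges by two-sample t-tests fitted on
    training subjects only, computes weighted-graph local clustering
    coefficients as node features, and classifies subjects with a per-window
    graph convolutional network (the functional connectivity matrix acting as
    weighted adjacency) whose window-wise outputs are aggregated by a
    multi-layer LSTM. Includes a synthetic two-group cohort simulator with
    planted, window-detectable connectivity differences so the whole pipeline
    is testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
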