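Package: fcnet
Title: Graph-Theoretic Analysis of Resting-State Functional Brain Networks
Version: 0.1.0
Authors@R: person("fcnet", "developers", role = c("aut", "cre"),
    email = "fcnet@example.org")
Description: Constructs functional connectomes from regional BOLD time series
    and analyses their topology: Pearson correlation matrices, sparsity
    thresholding over a cost grid, small-world metrics (clustering,
    characteristic path length, normalized gamma/lambda/sigma against
    degree-preserving rewired nulls), global/local/nodal efficiency and
    betweenness, trapezoidal integration of metric curves over the sparsity
    range, covariate-adjusted permutation group comparison with
    Benjamini-Hochberg false discovery rate control, and partial
    correlations with clinical variables. Includes a synthetic two-group
    BOLD cohort generator based on a Gaussian graphical model over a
    Watts-Strogatz ground-truth network.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
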