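Package: causalmix
Title: Causal Discovery for Mixed Continuous and Categorical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based causal discovery for tabular datasets that mix
    continuous and categorical variables. Learns a sparse undirected mixed
    graphical model (MGM) by penalized pseudo-likelihood with proximal
    gradient descent, selects the three edge-type penalties automatically
    from subsampling stability (StEPS), and refines and orients the graph
    with the order-independent PC-Stable algorithm using regression-based
    conditional-independence tests for mixed data. Includes Pref-Div
    feature pre-selection, a Gibbs-sampling simulator of mixed graphical
    models for benchmarking, and graph export to SIF and Cytoscape JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph,
    optparse
Config/testthat/edition: 3
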