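Package: kcliquenet
Title: K-Clique Percolation Analysis of Weighted Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the k-clique community organization of
    weighted semantic and free-association networks: maximal-clique based
    k-clique percolation profiles, the analytic Erdos-Renyi percolation
    threshold, per-edge clique statistics (edge clustering coefficient,
    edge clique number, binned weight-clustering fits), weight-threshold
    and node-removal perturbation experiments, and a triangle
    preferential-attachment growth model that reproduces the clique
    organization of free-association data, together with a config-driven
    pipeline for running the full experiment suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
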