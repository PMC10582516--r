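Package: bionetkit
Title: Topology, Community Structure and Annotation Statistics for
    Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for the topological analysis of biological
    (typically protein-protein interaction) networks: network
    construction from edge lists and standard graph formats, vertex
    annotation, centrality measures including semi-local centrality,
    discrete power-law degree-distribution fitting, entropy-rate
    perturbation analysis, modularity-based community detection with
    spectral fine-tuning and hierarchical re-clustering, consensus
    clustering with per-cluster robustness and per-vertex bridgeness,
    annotation-pair overlap/separation statistics with permutation
    significance, hypergeometric over-representation analysis, and
    bipartite (disease-gene) network projection with degree-preserving
    rewiring nulls. Results are returned as tibbles and fitted objects
    carry tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
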