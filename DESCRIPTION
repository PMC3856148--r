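Package: netpharm
Title: Network Pharmacology of Multi-Component Formulas on Weighted Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the action of multi-component herbal
    formulas and single-target drugs on a weighted protein-protein
    interaction network. Builds high-confidence weighted interactomes from
    STRING-style edge lists (with rescue of focus genes below the
    confidence threshold), constructs drug-target bipartite networks,
    performs hypergeometric pathway enrichment of target sets, propagates
    disease and drug seeds by random walk with restart, scores
    drug-disease association by the inner product of propagation vectors
    with a permutation z-score null model, and characterises the
    disease subnetwork by degree, betweenness and k-core decomposition.
    A synthetic-data generator produces weighted scale-free networks with
    planted disease modules, drug target sets and pathway collections so
    the whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
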