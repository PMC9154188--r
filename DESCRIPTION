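Package: netbackbone
Title: Backbone Extraction from Weighted, Bipartite, and Unweighted Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduces a complex network to its backbone: a sparse, unweighted
    (optionally signed) subgraph that preserves important structure. Implements
    the global threshold and disparity filter for weighted networks; the
    stochastic degree sequence model (SDSM), fixed degree sequence model
    (FDSM, via curveball sampling), and fixed row/column/fill null models for
    weighted bipartite projections; and a score/normalize/filter/connect
    sparsification framework for unweighted networks with L-Spar and Local
    Degree presets. Edge-level p-values, multiple-test corrections, signed
    two-tailed extraction, reduction statistics and narrative reporting are
    provided, along with readers and writers for edgelist, dense-matrix,
    Matrix Market and GraphML formats and seeded synthetic-network generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
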