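Package: nascentfold
Title: Structural Analysis of Protein Folding Pathway Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for 3D structural analysis of protein folding pathway
    intermediates. Implements TM-score rigid-body superposition for comparing
    partial and full nascent-chain conformations, extraction of "proxy"
    co-translational intermediates (prefix substructures of native
    structures), static and dynamic protein structure networks with
    graphlet-count features, logistic-regression structural classification
    comparing static versus dynamic network models, and folding-kinetics
    statistics (contact order, two-state pathway fraction). A deterministic
    synthetic-structure generator (ideal helices, strands, self-avoiding
    coils, hinged conformers, simulated co-translational pathways) makes
    every analysis stage reproducible without external structure downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
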