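Package: immunowire
Title: Quantitative Cell-Surface Receptor Interactome and Cell Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Immunowire", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring arrayed extracellular protein-interaction
    screens (Tukey median polish plate normalization, bait-prey orientation
    summing, hit selection, promiscuity filtering and ROC/PR benchmarking),
    for assembling an affinity-annotated cell-cell interactome from
    expression data (detection binarization, interaction keys, activation
    affinity-switch testing, eigenvector centrality of cell-type networks),
    for predicting relative cell-cell connectivity with a mass-action
    doublet kinetics model including in silico protein knockouts, for
    spatial receptor-ligand colocalization testing on spot-level spatial
    transcriptomics with a permuted-pair null, and for cell-cell interaction
    scoring from high-content imaging cell tables. A synthetic-data module
    generates every input with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
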