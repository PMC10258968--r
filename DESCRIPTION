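Package: boolvvv
Title: Verification, Validation and Visualization of Reaction-Contingency Boolean Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with bipartite reaction-contingency Boolean
    network models of cell signaling. Reads and writes models in the BoolNet
    text format, parses reaction/state node names to recover their semantics,
    and provides deterministic synchronous simulation with clamped nodes,
    attractor detection and rotation-aware attractor comparison. Verifies
    whole-model consistency by cycling a ligand on and off and mapping the
    reachable attractor space (meta-attractors, branching, traps), validates
    models with exhaustive stimulus/inhibitor truth tables and single-node
    sensitivity analysis, and scores model predictions against MIDAS-format
    experimental databases by mean squared error. Includes programmatic
    fixtures (a ligand-receptor-kinase-substrate cascade, random models, and
    a synthetic MIDAS generator) plus trajectory, comparison and regulatory
    graph visualizations with XGMML/GraphML export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
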