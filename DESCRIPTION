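Package: braingat
Title: Graph Attention Networks for Multimodal Brain Connectome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end graph classification of multimodal brain connectomes
    with a two-layer multi-head graph attention network (GAT). Builds a
    24-feature multimodal node description (morphology, structural- and
    functional-network nodal measures, nodal edge-distribution statistics)
    from structural and functional connectivity matrices over an 86-region
    Desikan-Killiany parcellation, balances cohorts with SMOTE on flattened
    connectomes, trains the attention network with a top-k node-embedding
    readout, and provides an interpretability layer: per-head fidelity
    scores, gradient saliency maps, averaged attention matrices, and
    correlation of salient node features with clinical variables. A
    synthetic-cohort generator with planted node-level effects makes every
    stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
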