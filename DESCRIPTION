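Package: slideTIS
Title: Tumor Invasion Scoring from Whole-Slide Patch Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-slide graphs from histology patch grids and patch
    embeddings, fits a graph attention network for tissue sub-compartment
    classification with Monte-Carlo dropout/DropEdge uncertainty estimation and
    label-propagation refinement, summarizes the contextualized patch embeddings
    into overlapping regions of interest with the Mapper algorithm from
    topological data analysis, and quantifies tumor invasion as the tumor row of
    an overlap-weighted tissue-class intermingling matrix (the Tumor Invasion
    Score). Includes a synthetic layered-colon slide simulator for validation and
    cohort-level, patient-clustered logistic association of invasion scores with
    cancer stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    igraph,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
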