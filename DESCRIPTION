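Package: spottype
Title: Marker-Based Cell-Type Annotation for Spatial Transcriptomics Spots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolution-free annotation of spatial transcriptomics spots from
    curated positive and negative marker gene sets. Implements marker-set
    enrichment scoring with gene specificity weights, per-spot and per-cluster
    label assignment, marker database parsing, validation and derivation from
    reference profiles, marker-panel coverage diagnostics, a 2D tissue simulator
    that places typed cells on a micron grid and probes them with fixed-diameter
    capture spots, and taxonomy-aware precision/recall/F1 benchmarking against
    ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
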