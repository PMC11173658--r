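Package: mphgcl
Title: Meta-Path Heterogeneous Graph Contrastive Learning for Drug-Drug
    Interaction Event Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-class drug-drug interaction (DDI) event prediction from a
    drug heterogeneous graph of chemical substructures, target proteins,
    enzymes, transport pathways and protein-protein interactions. Builds
    meta-path-based drug sub-graphs with PathSim similarity and top-K
    neighbor filtering, contrasts an average graph view against a three-level
    masking-augmented view through multi-head graph attention and semantic
    attention encoders, and trains with a combination of prediction,
    cross-view InfoNCE and supervised contrastive losses. Includes cold-start
    evaluation splits, frequency-grouped reporting, a synthetic data
    generator with planted cluster structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
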