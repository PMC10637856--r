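Package: moanet
Title: Mechanism-of-Action Subnetwork Inference from Typed Multi-Omics
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the mechanism of action (MoA) of a drug or gene
    perturbation from a typed, directed multi-omics interaction network.
    Drug-target, protein-protein and transcription-factor-gene regulatory
    interactions are merged into one reference network, restricted to a
    cell context by a TPM expression filter, and scored against a
    perturbation signature: for every differentially expressed endpoint
    all constrained shortest paths from the starting node are enumerated
    (the final edge must be a regulatory interaction leaving a
    transcription factor), the endpoint's false discovery rate is
    distributed over path edges as an m-th root penalty, penalties
    multiply across drug actions, and each edge's confidence is one minus
    its accumulated penalty. Top-confidence edges form a centric
    subnetwork and the highest-confidence constrained shortest path
    answers step-by-step MoA queries. A seeded synthetic-data generator
    with a planted drug-protein-TF-gene path makes the whole pipeline
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
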