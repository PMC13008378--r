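Package: specdiv
Title: Specialization-Diversity Analysis of Annotated Directed Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Entropy-based analysis of directed, weighted networks whose nodes
    carry categorical annotations (for example synapse-level connectomes with
    cell-type or lineage labels). Computes per-node specialization-diversity:
    the difference between the Shannon entropy of the average annotation
    connectivity vector of a node's partners and the average of their
    individual entropies, in its integrative (upstream-input) and distributive
    (downstream-output) motif variants. Includes entropic-hub ranking,
    pairwise entropic-distance null-model tests with two-sample
    Kolmogorov-Smirnov statistics, and a seeded synthetic generator of
    annotated networks with planted diversely-specialized hubs, planted
    same-specialization controls, and mirrored left-right node pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
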