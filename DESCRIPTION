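Package: domgraph
Title: Temporal Graphs of Molecular Transformations in Complex Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build snapshot-based temporal graphs from time-resolved
    molecular-formula peak tables, such as those produced by ultrahigh
    resolution mass spectrometry of dissolved organic matter. Enumerates
    potential chemical transformations between consecutive snapshots from a
    table of elemental transformation units, predicts likely transformations
    from simultaneous educt intensity loss and product intensity gain beyond
    a measurement error margin, converts the result to a lossless
    per-formula light graph, clusters it with weighted label propagation,
    and summarises transformation-unit shares, edge weights, and
    intensity-weighted molecular descriptors. Includes a seeded synthetic
    snapshot simulator with known ground-truth transformations for
    validation, plus GraphML, node/edge table, and graph-database script
    exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
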