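Package: corepeel
Title: Protein Complex Prediction in Interaction Networks by Core
    Decomposition and Peeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein complexes in large protein-protein
    interaction networks as overlapping dense subgraphs. Candidate
    clusters are seeded from the k-core decomposition of the network,
    trimmed to high-core ego-neighbourhoods, peeled down to a target
    density, and pruned of duplicate and near-duplicate sets. Includes
    the standard complex-matching quality measures (F-measure, Jaccard,
    precision-recall product, semantic similarity, and their aggregated
    score), hypergeometric GO-enrichment scoring with FDR correction,
    readers for edge-list, complex and GAF annotation formats, random
    prediction baselines, and synthetic benchmark generators with
    planted quasi-cliques and noise-edge injection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
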