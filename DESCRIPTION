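Package: binderclust
Title: Cluster, Rank and Visualize Binder Candidates from Structure-Prediction Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Triage for one-against-many AlphaFold-Multimer interaction
    screens. Given per-complex model outputs (coordinates, ranking
    confidences, ipTM/pTM/pLDDT scores and the predicted aligned error
    matrix), the package gates complexes by ipTM, trims bait and target
    chains to the regions confidently placed relative to the partner using
    the inter-chain PAE block, clusters the trimmed targets jointly by
    sequence and by fold, merges overlapping cluster assignments into joint
    clusters, selects each cluster's lowest-median-RMSD representative, and
    ranks clusters for inspection, emitting CSV tables, per-cluster
    directories and PyMOL command scripts. A synthetic screen generator
    with known ground truth supports end-to-end validation without real
    AlphaFold output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
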