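Package: cranet
Title: Anatomical Network Analysis of Skull Bone-Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models skulls as networks of bone contacts and analyses their
    morphological organization. Identifies connectivity modules by
    hierarchical clustering of topological overlap with Newman-modularity
    (Q) partition selection, quantifies morphological complexity with five
    network metrics (node count, edge count, density, mean clustering
    coefficient, degree heterogeneity), and tests the near-decomposability
    hypothesis with Abouheif and Blomberg phylogenetic-signal tests and
    Pearson correlations of phylogenetic independent contrasts. Includes
    seeded generators for bilaterally symmetric skull-like networks,
    pure-birth phylogenies and Brownian-motion traits, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
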