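Package: mgrnet
Title: miRNA-Gene Regulatory Network Discovery from Combined Target
    Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers miRNA-gene regulatory networks from heterogeneous
    miRNA-target prediction scores. A positive-unlabeled (PU) bagged
    ensemble combines the scores of several upstream prediction
    algorithms into a single interaction reliability score under the
    selected-completely-at-random assumption; a hierarchical overlapping
    biclustering procedure then extracts cohesive, possibly overlapping
    miRNA-gene modules from the weighted bipartite interaction matrix by
    greedy biclique aggregation, SVM-based overlap detection and
    quality-constrained merging; modules are finally ranked by Gene
    Ontology functional coherence using SimGIC semantic similarity and a
    one-tailed t-test. Includes seeded synthetic-data generators (planted
    bicluster matrices, PU-labelled score vectors, toy ontologies) so the
    whole pipeline is testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    e1071,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'biclique.R'
    'hierarchy.R'
    'interaction-io.R'
    'ontology.R'
    'ranking.R'
    'pipeline.R'
    'pu-ensemble.R'
    'synthetic.R'
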