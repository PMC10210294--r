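Package: pdaGCN
Title: Graph Convolutional Prediction of piRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts associations between Piwi-interacting RNAs (piRNAs)
    and human diseases by link prediction on a two-layer heterogeneous
    network. Sequence similarity (global Needleman-Wunsch alignment),
    MeSH-style directed-acyclic-graph semantic similarity and Gaussian
    interaction profile kernels are fused and assembled with the known
    association matrix into a heterogeneous graph; a layer-attention graph
    convolutional encoder produces low-dimensional node embeddings, a
    bias-free non-linear embedding transformation module maps piRNA
    embeddings into the disease embedding space, and pairs are scored by
    cosine similarity. Training minimises a class-imbalance-weighted
    cross-entropy with Adam, a triangular cyclic learning rate and node /
    regular dropout. Includes leakage-safe five-fold cross-validation,
    candidate ranking, and a synthetic-data generator with planted cluster
    structure so the full pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
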