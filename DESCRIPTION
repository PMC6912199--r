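Package: stim
Title: Similarity- and Topology-Based Prediction of Disease-miRNA Associations
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease-miRNA associations from a heterogeneous bilayer
    network. Builds a disease similarity network from gene-set log-likelihood
    scores and a weighted four-source miRNA similarity network, learns latent
    topology vectors for every node with DeepWalk (truncated random walks plus
    SkipGram trained through a hierarchical softmax), compresses similarity
    features with an autoencoder, classifies candidate pairs with two deep
    (cascade) forest models, and fuses the two scores with a convex weight.
    Includes a planted-partition simulator for end-to-end benchmarking and a
    per-disease five-fold cross-validation evaluator reporting AUC and
    precision/recall at k.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
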