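Package: linkgcn
Title: Linear Residual Graph Convolution for Bipartite Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between non-coding RNAs and drug-resistance
    phenotypes from a verified bipartite association network alone. Builds the
    symmetric spectrally normalized adjacency of the self-looped bipartite
    graph, propagates node embeddings through K linear graph-convolution layers
    (no nonlinear activations), and scores ncRNA-drug pairs by residually
    accumulating per-layer embedding dot products, which counters
    over-smoothing. Training minimizes a Bayesian Personalized Ranking loss
    with L2 regularization by Adam. Includes k-fold cross-validation with
    balanced negative sampling (AUC, AUPR, accuracy, precision, recall, F1),
    candidate ranking for a query drug, a synthetic generator with planted
    block structure, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
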