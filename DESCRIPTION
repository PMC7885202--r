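Package: splicedarts
Title: Differentiable Architecture Search for Splice-Site Classification
Version: 0.1.0
Authors@R:
    person("Sam", "Ellis", email = "sam.ellis@example.org",
           role = c("aut", "cre"))
Description: A desk-scale engine for discovering convolutional network
    architectures that classify true versus false splice sites in raw DNA
    sequences.  Sequences are one-hot encoded as (length x 4) tensors and a
    cell-based search space of separable, dilated and asymmetric convolutions
    plus pooling primitives is relaxed continuously: every edge of the cell
    DAG carries a softmax-weighted mixture of candidate operations whose
    mixing coefficients are optimized jointly with the network weights by
    bilevel gradient descent.  The best mixture is discretized into a cell
    genotype, retrained as a fixed network, and evaluated with the standard
    binary-classification metric suite (accuracy, sensitivity, specificity,
    F-score, AUC).  Includes a synthetic planted-motif sequence generator so
    that search, training and evaluation are fully testable offline, and a
    command-line interface covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
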