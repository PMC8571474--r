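Package: traceblocks
Title: Tracing-Difficulty Classification of 3D Neuron Image Blocks
Version: 0.1.0
Authors@R:
    person("Trace", "Blocks Developers", email = "traceblocks@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing how difficult 3D light-microscopy neuron
    image blocks are for automatic tracing algorithms. Partitions neuron
    volumes into overlapped 32x64x64 blocks anchored every 100 nodes along a
    gold-standard SWC reconstruction, computes reconstruction-similarity
    metrics (entire-structure average distance, different-structure average,
    percentage of different structures) and L-Measure-style morphometrics,
    auto-labels blocks as low or high tracing difficulty with a small
    fully-connected classifier, and trains a three-module classifier (3D
    residual network over image blocks, morphometric feature network,
    label-conditioned LSTMs over block sequences, and a fusion head). A
    seed-reproducible synthetic neuron-image simulator makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
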