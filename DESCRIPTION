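Package: netdistill
Title: Distilling Temporal Contact Networks into Static Graphs for
    Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reduce timestamped contact sequences (i, j, t) to
    static networks suited to network epidemiology.  Implements three
    parameterized representations -- time-slice, ongoing (concurrent
    partnership) and exponential-threshold networks -- together with an
    event-driven SIR simulator that runs directly on the contact
    sequence, so that each representation can be scored by how well
    static degree or coreness predicts per-seed expected outbreak size
    (Spearman rank correlation), and the representation parameters
    optimized over a grid.  Also provides whole-sequence temporal
    statistics (burstiness), static-network diagnostics with a
    degree-preserving rewiring null model, and a synthetic
    temporal-network generator (configuration model with truncated
    power-law degrees, per-edge activity intervals and bursty
    interevent times) for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
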