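Package: complexome
Title: Bipartite Network Analysis and Global Optimization for Protein Complexomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the complexome of an organism -- the set of
    protein complexes and their component proteins -- as a bipartite network
    with weighted one-mode projections, together with two global optimization
    methods built on that organisation: linear-programming estimation of
    complex copy numbers (with imputation of unknown protein abundances) and
    per-function minimum set cover assignment of biological functions to
    complexes, including a high-confidence filter that keeps only assignments
    present in every optimal cover. Includes generating-function predictions
    of projected degree distributions, exponential versus power-law fits of
    cumulative degree distributions, a train/test validation harness, and a
    synthetic complexome generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
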