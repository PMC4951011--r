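Package: seedpath
Title: Seed-Based Shortest-Path Gene Prioritization on Weighted
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate function-associated genes from a weighted
    protein-protein interaction network and a set of validated ("seed") genes.
    Interaction confidence scores (STRING-style combined scores in [150, 999])
    are converted to edge weights w = 1000 - score, all shortest paths between
    seed pairs are counted combinatorially, inner nodes are scored by the
    number of seed-pair shortest paths passing through them (a seed-restricted
    path betweenness), and a permutation test over random gene sets of the
    same size yields a per-gene false discovery rate FDR(g) = M/N; genes with
    FDR below a threshold are reported as candidates. Includes a STRING
    protein.links parser, a synthetic planted-module network generator for
    benchmarking, recovery metrics, and a checkpointable pipeline with a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
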