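Package: fosnet
Title: Functional Brain Networks from Regional c-fos Counts
Version: 0.1.0
Authors@R:
    person("fosnet", "authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Builds interregional functional connectivity networks from
    per-animal counts of c-fos expressing cells across brain regions.
    Computes per-group Pearson correlation matrices, derives a pooled
    mean-plus-one-SD edge-retention threshold, constructs weighted
    undirected networks, and measures degree, betweenness, nodal and
    global efficiency and clustering with the conventions used in
    immediate-early-gene connectomics (unweighted geodesics for
    betweenness, inverse-correlation edge lengths for efficiency).
    Provides clustering-matched Watts-Strogatz small-world null
    comparisons, leading-eigenvector community detection, native
    Kruskal-Wallis and Mann-Whitney tests, and a synthetic-cohort
    generator with planted correlation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
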