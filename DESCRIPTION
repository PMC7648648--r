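Package: tierclust
Title: Iterative Tiered Clustering and Trajectory Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recursive community-detection clustering of droplet single-cell
    RNA-seq data in which every candidate sub-clustering must pass a
    differential-expression quality gate before it becomes a new tier,
    yielding a hierarchical tree of cell populations. Includes the
    surrounding pipeline stages: a negative-binomial count simulator with
    known hierarchical cell types, batch effects, doublets and continuous
    differentiation gradients; UMI/gene-count quality control with
    mutually-exclusive-marker doublet flagging; log counts-per-10k
    normalization, variable-gene selection, PCA embedding and centroid
    batch correction; marker ranking, unique-gene tables and gene-set
    scoring; minimum-spanning-tree pseudotime with fixed-size binning and
    trajectory differential expression; and clone-frequency statistics for
    lineage-tracing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
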