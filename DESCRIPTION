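Package: methylgraph
Title: Graph-Based Imputation of Single-Cell CpG Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes missing CpG methylation states in sparse single-cell
    bisulfite-sequencing data by casting the cell-by-locus binary methylation
    matrix as a bipartite graph and predicting each masked state from its
    locus-aware neighboring subgraph. A relational graph convolution network
    with two-basis weight sharing passes messages over methylated and
    unmethylated edges separately; cross-layer node embeddings are pooled by
    a small convolutional stack and a sigmoid multilayer perceptron scores
    the target state. Includes readers for bismark-style coverage files,
    chromosome-wise train/validation/test splitting, a synthetic methylome
    simulator with cell-type block structure, evaluation stratified by cell
    and by window entropy, embedding-based subgraph reports with bipartite
    graph export, and Spearman-similarity hierarchical clustering of raw and
    imputed matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    igraph,
    mclust,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
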