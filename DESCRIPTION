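Package: adenet
Title: Adaptive Elastic-Net Gene Regulatory Networks from Single-Cell Multiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step regularized-regression inference of gene regulatory
    networks from paired single-nucleus RNA and ATAC measurements. A first
    adaptive elastic-net stage models each gene's expression on the
    accessibility of chromatin peaks within 500 kb of its transcription
    start site to nominate cis-regulatory elements (CREs); motif scanning
    over significant CREs and promoters nominates candidate transcription
    factors; a second adaptive elastic-net stage models gene expression on
    TF expression to yield a signed, weighted TF-to-gene network. Includes
    bootstrap coefficient significance, pseudocell micropooling, regulatory
    scoring along a two-state axis, PageRank and betweenness centrality,
    in-silico TF perturbation, AIC-based model comparison, and a synthetic
    multiome generator with a planted ground-truth network for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'enet.R'
    'tf.R'
    'compare.R'
    'ranges.R'
    'cre.R'
    'io.R'
    'motif.R'
    'normalize.R'
    'pseudocell.R'
    'scoring.R'
    'pipeline.R'
    'simulate.R'
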