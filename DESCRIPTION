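Package: stromatlas
Title: Clustering, Cross-Species Label Transfer and Trajectory Analysis for
    Intestinal Mesenchyme Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipelines for droplet (10x-style) and
    microfluidic (C1-style) single-cell RNA-seq of intestinal stromal cells:
    barcode calling by density local minima, mitochondrial and control-cell QC,
    deconvolution size factors and log normalization, in-silico technical
    control genes with factor removal, signed-hybrid co-expression networks
    with dynamic tree cut, non-negative matrix factorization consensus
    clustering with rank selection against permuted controls, AUC marker
    ranking and negative-binomial differential expression with latent
    covariates, hypergeometric gene-set enrichment, cross-species random
    forest label transfer with ortholog filtering, SMOTE balancing and
    recursive feature elimination, diffusion maps with diffusion pseudotime,
    gene-pair cell-cycle scoring, and batch-mixing entropy diagnostics. A
    bundled synthetic-data generator with ground truth makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    scran,
    sva,
    fgsea,
    randomForest,
    Rtsne,
    igraph,
    cluster,
    MASS,
    ape,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse
biocViews: SingleCell, Transcriptomics, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
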