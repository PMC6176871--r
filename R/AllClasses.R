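#' @import methods
#' @importFrom stats approx as.dist cophenetic cor cutree density dist
#'   glm.fit hclust loess median p.adjust phyper pnorm prcomp predict
#'   quantile rbeta rlnorm rnbinom rnorm rpois runif sd setNames t.test var
#'   binom.test fisher.test model.matrix coef poisson mad bw.nrd0
#' @importFrom utils head read.delim write.table
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic droplet experiment generator. The defaults
#' describe the reference simulation used throughout the package's tests:
#' five mesenchymal-like clusters of 200 cells each, 2,000 genes of which a
#' tenth are cluster markers at a log2 fold change of 2, two experimental
#' batches, 4,000 ambient (empty) barcodes at a mean of 100 UMIs against a
#' cell mode of 5,000 UMIs, a 2% mean mitochondrial fraction, and a 5%
#' spike-in of transgene-bearing control cells.
#'
#' @slot n_genes number of genes (excluding the 13 mitochondrial genes and
#'   the control transgene, which are appended).
#' @slot n_cells_per_cluster integer vector, cells per cluster.
#' @slot de_fraction fraction of genes assigned as cluster markers.
#' @slot logfc log2 fold-change magnitude of marker genes in their cluster.
#' @slot nb_dispersion negative-binomial dispersion phi (variance mu+phi*mu^2).
#' @slot n_batches number of batches.
#' @slot batch_logfc_sd SD of gene-wise log2 multiplicative batch factors.
#' @slot ambient_barcodes number of empty barcodes.
#' @slot ambient_mean_umi,cell_mean_umi expected totals of the two barcode
#'   modes.
#' @slot mito_fraction_mean mean mitochondrial UMI fraction of real cells.
#' @slot control_cell_fraction fraction of cells that are spiked control
#'   cells carrying the transgene.
#' @slot mito_prefix gene-symbol prefix of the mitochondrial genes.
#' @slot seed integer seed; fully determines the output.
#' @export
setClass("SimConfig", representation(
    n_genes = "integer",
    n_cells_per_cluster = "integer",
    de_fraction = "numeric",
    logfc = "numeric",
    nb_dispersion = "numeric",
    n_batches = "integer",
    batch_logfc_sd = "numeric",
    ambient_barcodes = "integer",
    ambient_mean_umi = "numeric",
    cell_mean_umi = "numeric",
    mito_fraction_mean = "numeric",
    control_cell_fraction = "numeric",
    mito_prefix = "character",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(object@n_genes, object@n_cells_per_cluster, object@n_batches,
             object@ambient_barcodes)
    if (any(cnt < 0L)) msg <- c(msg, "all counts must be >= 0")
    if (length(object@n_cells_per_cluster) < 1L)
        msg <- c(msg, "need at least one cluster")
    fr <- c(object@de_fraction, object@mito_fraction_mean,
            object@control_cell_fraction)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0,1]")
    if (any(object@nb_dispersion < 0)) msg <- c(msg, "nb_dispersion must be >= 0")
    if (object@batch_logfc_sd < 0) msg <- c(msg, "batch_logfc_sd must be >= 0")
    if (object@ambient_mean_umi <= 0 || object@cell_mean_umi <= 0)
        msg <- c(msg, "mode means must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param n_genes,n_cells_per_cluster,de_fraction,logfc,nb_dispersion
#'   see \linkS4class{SimConfig}.
#' @param n_batches,batch_logfc_sd,ambient_barcodes,ambient_mean_umi
#'   see \linkS4class{SimConfig}.
#' @param cell_mean_umi,mito_fraction_mean,control_cell_fraction,mito_prefix
#'   see \linkS4class{SimConfig}.
#' @param seed integer seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(n_genes = 200, n_cells_per_cluster = c(50, 50), seed = 7)
#' @export
simConfig <- function(n_genes = 2000L,
                      n_cells_per_cluster = rep(200L, 5L),
                      de_fraction = 0.1,
                      logfc = 2,
                      nb_dispersion = 0.3,
                      n_batches = 2L,
                      batch_logfc_sd = 0.15,
                      ambient_barcodes = 4000L,
                      ambient_mean_umi = 100,
                      cell_mean_umi = 5000,
                      mito_fraction_mean = 0.02,
                      control_cell_fraction = 0.05,
                      mito_prefix = "MT-",
                      seed = 1L) {
    new("SimConfig",
        n_genes = as.integer(n_genes),
        n_cells_per_cluster = as.integer(n_cells_per_cluster),
        de_fraction = de_fraction,
        logfc = logfc,
        nb_dispersion = nb_dispersion,
        n_batches = as.integer(n_batches),
        batch_logfc_sd = batch_logfc_sd,
        ambient_barcodes = as.integer(ambient_barcodes),
        ambient_mean_umi = ambient_mean_umi,
        cell_mean_umi = cell_mean_umi,
        mito_fraction_mean = mito_fraction_mean,
        control_cell_fraction = control_cell_fraction,
        mito_prefix = mito_prefix,
        seed = as.integer(seed))
}

#' @describeIn SimConfig-class compact display.
#' @param object a \code{SimConfig}.
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_genes, "genes,",
        sum(object@n_cells_per_cluster), "cells in",
        length(object@n_cells_per_cluster), "clusters,",
        object@ambient_barcodes, "ambient barcodes, seed", object@seed, "\n")
})

#' Gene co-expression module assignment
#'
#' Result of dynamic tree cut on a co-expression dissimilarity: a module
#' label per gene, with 0 meaning unassigned.
#'
#' @slot module_of named integer vector over genes; 0 = unassigned.
#' @slot module_sizes integer vector of module sizes, named by module label.
#' @export
setClass("GeneModuleSet", representation(
    module_of = "integer",
    module_sizes = "integer"
))

setValidity("GeneModuleSet", function(object) {
    m <- object@module_of
    if (any(m < 0L)) return("module labels must be >= 0")
    lab <- sort(unique(m[m > 0L]))
    if (length(lab) && !identical(lab, seq_along(lab)))
        return("module labels must be contiguous 1..K")
    TRUE
})

#' @describeIn GeneModuleSet-class gene -> module assignment vector.
#' @param x a \code{GeneModuleSet}.
#' @export
moduleOf <- function(x) x@module_of

#' @describeIn GeneModuleSet-class module sizes.
#' @export
moduleSizes <- function(x) x@module_sizes

#' @describeIn GeneModuleSet-class genes assigned to any module.
#' @export
moduleGenes <- function(x) names(x@module_of)[x@module_of > 0L]

#' @describeIn GeneModuleSet-class compact display.
#' @param object a \code{GeneModuleSet}.
#' @export
setMethod("show", "GeneModuleSet", function(object) {
    k <- length(object@module_sizes)
    cat("GeneModuleSet:", k, "modules over", length(object@module_of),
        "genes (", sum(object@module_of == 0L), "unassigned )\n")
    if (k) print(object@module_sizes)
})

#' NMF consensus clustering result
#'
#' Per-rank consensus matrices (cell-by-cell co-assignment frequencies over
#' repeated random-initialization NMF runs), their quality metrics, the
#' metrics of a permuted-data control, the chosen rank, and the cell labels
#' at that rank.
#'
#' @slot rank_range integer vector of surveyed ranks.
#' @slot consensus list of cells-by-cells consensus matrices, one per rank.
#' @slot metrics data.frame with columns rank, cophenetic, silhouette,
#'   dispersion, rss.
#' @slot control_metrics same shape, computed on permuted data (possibly
#'   empty).
#' @slot chosen_rank integer.
#' @slot labels integer cluster labels at the chosen rank.
#' @export
setClass("ConsensusClustering", representation(
    rank_range = "integer",
    consensus = "list",
    metrics = "data.frame",
    control_metrics = "data.frame",
    chosen_rank = "integer",
    labels = "integer"
))

setValidity("ConsensusClustering", function(object) {
    for (C in object@consensus) {
        if (max(abs(C - t(C))) > 1e-8) return("consensus must be symmetric")
        if (any(C < -1e-8 | C > 1 + 1e-8)) return("consensus entries in [0,1]")
        if (max(abs(diag(C) - 1)) > 1e-8) return("consensus diagonal must be 1")
    }
    TRUE
})

#' @describeIn ConsensusClustering-class the selected factorization rank.
#' @param x a \code{ConsensusClustering}.
#' @export
chosenRank <- function(x) x@chosen_rank

#' @describeIn ConsensusClustering-class cell labels at the chosen rank.
#' @export
consensusLabels <- function(x) x@labels

#' @describeIn ConsensusClustering-class consensus matrix at a given rank.
#' @param rank surveyed rank (defaults to the chosen rank).
#' @export
consensusMatrix <- function(x, rank = chosenRank(x)) {
    i <- match(rank, x@rank_range)
    if (is.na(i)) stop("rank ", rank, " was not surveyed")
    x@consensus[[i]]
}

#' @describeIn ConsensusClustering-class per-rank quality metrics.
#' @export
rankMetrics <- function(x) x@metrics

#' @describeIn ConsensusClustering-class compact display.
#' @param object a \code{ConsensusClustering}.
#' @export
setMethod("show", "ConsensusClustering", function(object) {
    cat("ConsensusClustering over ranks",
        paste(range(object@rank_range), collapse = ".."),
        "- chosen rank:", object@chosen_rank, "\n")
    print(object@metrics, row.names = FALSE, digits = 4)
})

#' Diffusion map and pseudotime result
#'
#' Eigen-decomposition of the density-normalized diffusion operator built on
#' a k-nearest-neighbor Gaussian kernel with per-cell local bandwidth, plus
#' (optionally) diffusion pseudotime from a root cell.
#'
#' @slot eigenvalues non-trivial operator eigenvalues, decreasing.
#' @slot components cells-by-d matrix of diffusion components.
#' @slot pseudotime per-cell pseudotime (NA until computed).
#' @slot root_cell root cell name or index as character ("" until set).
#' @slot in_largest_component logical flag per cell; FALSE marks cells
#'   outside the largest connected kNN component (their coordinates are NA).
#' @slot params list with k_nn and sigma rule.
#' @export
setClass("DiffusionResult", representation(
    eigenvalues = "numeric",
    components = "matrix",
    pseudotime = "numeric",
    root_cell = "character",
    in_largest_component = "logical",
    params = "list"
))

#' @describeIn DiffusionResult-class diffusion components (cells x d).
#' @param x a \code{DiffusionResult}.
#' @export
diffusionComponents <- function(x) x@components

#' @describeIn DiffusionResult-class operator eigenvalues.
#' @export
diffusionEigenvalues <- function(x) x@eigenvalues

#' @describeIn DiffusionResult-class per-cell pseudotime.
#' @export
pseudotime <- function(x) x@pseudotime

#' @describeIn DiffusionResult-class compact display.
#' @param object a \code{DiffusionResult}.
#' @export
setMethod("show", "DiffusionResult", function(object) {
    cat("DiffusionResult:", nrow(object@components), "cells,",
        ncol(object@components), "components; eigenvalues",
        paste(signif(head(object@eigenvalues, 3), 3), collapse = ", "),
        "...\n")
    if (nzchar(object@root_cell))
        cat("  pseudotime from root", object@root_cell, "\n")
})

#' Low-dimensional embedding
#'
#' @slot coords cells-by-d coordinate matrix.
#' @slot method one of "pca", "tsne", "diffusion".
#' @slot explained_variance per-component variance fraction (PCA).
#' @slot kl_divergence final KL divergence (t-SNE; of all runs, the selected
#'   run first).
#' @export
setClass("Embedding", representation(
    coords = "matrix",
    method = "character",
    explained_variance = "numeric",
    kl_divergence = "numeric"
))

#' @describeIn Embedding-class coordinate matrix.
#' @param x an \code{Embedding}.
#' @export
embeddingCoords <- function(x) x@coords

#' @describeIn Embedding-class compact display.
#' @param object an \code{Embedding}.
#' @export
setMethod("show", "Embedding", function(object) {
    cat("Embedding (", object@method, "): ", nrow(object@coords), " cells x ",
        ncol(object@coords), " dims\n", sep = "")
})

#' Validate an ortholog map table
#'
#' An ortholog map is a data.frame with columns \code{gene_A}, \code{gene_B},
#' \code{homology_class} (one2one / one2many / many2one / many2many),
#' \code{pct_identity_AtoB} and \code{pct_identity_BtoA}. Identities must lie
#' in [0,100] and (gene_A, gene_B) pairs must be unique.
#'
#' @param map data.frame to validate.
#' @return The map, invisibly, after checking the invariants.
#' @export
validateOrthologMap <- function(map) {
    need <- c("gene_A", "gene_B", "homology_class",
              "pct_identity_AtoB", "pct_identity_BtoA")
    miss <- setdiff(need, colnames(map))
    if (length(miss)) stop("ortholog map lacks columns: ",
                           paste(miss, collapse = ", "))
    cls <- c("one2one", "one2many", "many2one", "many2many")
    if (!all(map$homology_class %in% cls))
        stop("unknown homology_class values")
    idn <- c(map$pct_identity_AtoB, map$pct_identity_BtoA)
    idn <- idn[!is.na(idn)]
    if (any(idn < 0 | idn > 100)) stop("percent identities must lie in [0,100]")
    if (anyDuplicated(paste(map$gene_A, map$gene_B)))
        stop("duplicate (gene_A, gene_B) pairs")
    invisible(map)
}
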