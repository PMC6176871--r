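#' Signed-hybrid co-expression adjacency
#'
#' Pairwise Pearson correlation of genes across cells with negative
#' correlations set to zero (the "signed-hybrid" convention), raised to the
#' soft-thresholding power beta: a_ij = max(cor(i,j), 0)^beta, diagonal 1.
#' Zero-variance genes get zero correlation with a warning.
#'
#' @param expr genes-by-cells expression matrix (>= 3 cells).
#' @param beta soft power (default 4).
#' @return gene-by-gene adjacency matrix; the corresponding dissimilarity is
#'   \code{1 - adjacency}.
#' @export
signedHybridAdjacency <- function(expr, beta = 4) {
    if (ncol(expr) < 3L) stop("need at least 3 cells")
    v <- apply(expr, 1, var)
    if (any(v == 0))
        warning(sum(v == 0), " zero-variance genes; their correlations are 0")
    r <- suppressWarnings(cor(t(expr)))
    r[is.na(r)] <- 0
    a <- pmax(r, 0)^beta
    diag(a) <- 1
    dimnames(a) <- list(rownames(expr), rownames(expr))
    a
}

#' Prune low-confidence network edges
#'
#' Edges between gene pairs that are co-detected at "high confidence" (both
#' genes above \code{hi_conf_expr} on the normalized count scale) in fewer
#' than \code{hi_conf_min_cells} cells are removed by setting their
#' dissimilarity to 1.
#'
#' @param dissim gene-by-gene dissimilarity in [0,1].
#' @param expr genes-by-cells matrix on the scale of \code{hi_conf_expr}
#'   (normalized counts).
#' @param hi_conf_expr high-confidence detection threshold (default 6,
#'   midpoint of the working range 5-8).
#' @param hi_conf_min_cells minimum co-detecting cells (default 3).
#' @return Pruned dissimilarity matrix.
#' @export
confidencePrune <- function(dissim, expr, hi_conf_expr = 6,
                            hi_conf_min_cells = 3) {
    stopifnot(identical(rownames(dissim), rownames(expr)))
    b <- expr > hi_conf_expr
    co <- b %*% t(b)    # cells co-detecting both genes at high confidence
    cut <- co < hi_conf_min_cells
    diag(cut) <- FALSE
    dissim[cut] <- 1
    dissim
}

# mean pairwise dissimilarity among a set of leaves ("core scatter")
.branch_scatter <- function(dissim, leaves) {
    if (length(leaves) < 2L) return(0)
    mean(dissim[leaves, leaves][upper.tri(diag(length(leaves)))])
}

#' Detect gene modules by adaptive dendrogram cutting
#'
#' Genes are hierarchically clustered by average linkage on the
#' dissimilarity; modules are branches of the dendrogram found by a
#' top-down adaptive cut. An initial cut just below the dendrogram top
#' defines coarse branches; each branch is recursively split at its highest
#' merge whenever both sub-branches hold at least \code{min_module_size}
#' genes and the relative height gap of the split exceeds a threshold that
#' shrinks as \code{deep_split} grows (split sensitivity 0..4; larger values
#' give more, smaller modules). A final branch becomes a module when its
#' mean within-branch dissimilarity (core scatter) stays below the cut
#' height; all other genes are labeled 0 (unassigned).
#'
#' @param dissim gene-by-gene dissimilarity in [0,1].
#' @param deep_split integer 0..4 (default 3).
#' @param min_module_size minimum module size (default 30).
#' @return A \linkS4class{GeneModuleSet}; labels are renumbered by
#'   decreasing module size.
#' @export
dynamicTreeModules <- function(dissim, deep_split = 3, min_module_size = 30) {
    stopifnot(deep_split %in% 0:4, min_module_size >= 2)
    genes <- rownames(dissim)
    G <- length(genes)
    if (G < min_module_size) {
        warning("fewer genes than min_module_size; all genes unassigned")
        return(new("GeneModuleSet",
                   module_of = setNames(rep(0L, G), genes),
                   module_sizes = integer()))
    }
    hc <- hclust(as.dist(dissim), method = "average")
    hmax <- max(hc$height)
    cut_height <- 0.99 * hmax
    # split sensitivity: {0..4} -> scatter cap {0.64,...,0.95}; the gap
    # required to accept a split shrinks as deep_split grows
    scatter_cap <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
    min_gap <- (1 - scatter_cap) * 3 / 4

    # leaves under each merge node
    leaves_of <- vector("list", nrow(hc$merge))
    node_members <- function(i) {
        if (i < 0) return(-i)
        leaves_of[[i]]
    }
    for (i in seq_len(nrow(hc$merge)))
        leaves_of[[i]] <- c(node_members(hc$merge[i, 1]),
                            node_members(hc$merge[i, 2]))

    modules <- list()
    descend <- function(node) {  # node: positive merge index
        kids <- hc$merge[node, ]
        sizes <- vapply(kids, function(k) length(node_members(k)), integer(1))
        kid_h <- vapply(kids, function(k) if (k < 0) 0 else hc$height[k],
                        numeric(1))
        gap <- (hc$height[node] - max(kid_h)) / cut_height
        if (all(sizes >= min_module_size) && gap >= min_gap) {
            for (k in kids) if (k > 0) descend(k) # both sides big: split
        } else {
            modules[[length(modules) + 1L]] <<- node_members(node)
        }
    }
    # top-level branches: merge nodes beneath the cut whose parent merge
    # (if any) lies above it
    parent <- rep(NA_integer_, nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge)))
        for (k in hc$merge[i, ]) if (k > 0) parent[k] <- i
    top <- which(hc$height <= cut_height &
                 (is.na(parent) | hc$height[parent] > cut_height))
    for (node in top) descend(node)

    module_of <- setNames(rep(0L, G), genes)
    lab <- 0L
    for (mem in modules) {
        if (length(mem) < min_module_size) next
        if (.branch_scatter(dissim, mem) >= cut_height) next
        lab <- lab + 1L
        module_of[mem] <- lab
    }
    if (lab > 0L) {
        sz <- table(module_of[module_of > 0L])
        ord <- order(-as.integer(sz))
        remap <- setNames(seq_along(ord), names(sz)[ord])
        module_of[module_of > 0L] <-
            as.integer(remap[as.character(module_of[module_of > 0L])])
    }
    sizes <- if (lab > 0L) {
        s <- table(factor(module_of[module_of > 0L]))
        setNames(as.integer(s), names(s))
    } else integer()
    new("GeneModuleSet", module_of = module_of, module_sizes = sizes)
}

#' Permute expression values independently per gene
#'
#' Randomization control for consensus clustering: each gene's values are
#' independently permuted across cells, preserving gene marginals while
#' destroying gene-gene and cell structure.
#'
#' @param expr genes-by-cells matrix.
#' @param seed integer seed.
#' @return Matrix of the same shape and dimnames.
#' @export
permuteControl <- function(expr, seed = 1L) {
    set.seed(seed)
    out <- t(apply(expr, 1, sample))
    dimnames(out) <- dimnames(expr)
    out
}
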