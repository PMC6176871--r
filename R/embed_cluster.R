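#' Principal component analysis of cells
#'
#' PCA of cells over the selected genes (centered and unit-scaled per gene;
#' zero-variance genes are dropped). Components are ordered by decreasing
#' variance and carry a deterministic sign convention: the largest-magnitude
#' gene loading of each component is positive.
#'
#' @param expr genes-by-cells log-expression matrix.
#' @param n_components number of components to return.
#' @param variable_genes genes to use (default: all).
#' @param scale. scale genes to unit variance (default TRUE).
#' @return An \linkS4class{Embedding} with method "pca"; loadings are kept
#'   in \code{attr(coords, "rotation")}.
#' @export
pcaEmbed <- function(expr, n_components = 20, variable_genes = rownames(expr),
                     scale. = TRUE) {
    sub <- expr[intersect(variable_genes, rownames(expr)), , drop = FALSE]
    sub <- sub[apply(sub, 1, var) > 1e-12, , drop = FALSE]
    if (n_components > min(dim(sub)))
        stop("n_components exceeds the matrix rank bound")
    pc <- prcomp(t(sub), center = TRUE, scale. = scale., rank. = n_components)
    # sign convention: dominant loading positive
    for (j in seq_len(ncol(pc$rotation))) {
        i <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[i, j] < 0) {
            pc$rotation[, j] <- -pc$rotation[, j]
            pc$x[, j] <- -pc$x[, j]
        }
    }
    coords <- pc$x
    rownames(coords) <- colnames(sub)
    attr(coords, "rotation") <- pc$rotation
    new("Embedding", coords = coords, method = "pca",
        explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncol(coords))],
        kl_divergence = numeric())
}

#' Jackstraw significance of principal components
#'
#' Per replicate, a small random fraction of genes is permuted across cells
#' and the decomposition recomputed; the permuted genes' squared loadings
#' form the null and the unpermuted genes' squared loadings, averaged over
#' replicates, the observed statistics. Because both are measured in the
#' same refits, permuted and unpermuted genes are exchangeable under the
#' null and the per-gene p-values are calibrated. A component is significant
#' when gene p-values below \code{alpha} are enriched beyond the uniform
#' expectation (one-sided binomial test); the largest significant prefix
#' 1..m is returned. With \code{perm_fraction = 1} every gene is permuted,
#' no observed statistics remain, and nothing is significant.
#'
#' @param expr genes-by-cells matrix.
#' @param n_pc components to assess.
#' @param perm_fraction fraction of genes permuted per replicate.
#' @param n_reps permutation replicates (>= 20).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return Integer vector of significant component indices (possibly empty).
#' @export
jackstrawPcs <- function(expr, n_pc = 10, perm_fraction = 0.01, n_reps = 100,
                         alpha = 0.05, seed = 1L) {
    stopifnot(n_reps >= 20)
    set.seed(seed)
    sub <- expr[apply(expr, 1, var) > 1e-12, , drop = FALSE]
    G <- nrow(sub)
    n_pc <- min(n_pc, min(dim(sub)) - 1L)
    m <- max(1L, round(perm_fraction * G))
    if (m >= G) return(integer())
    zs <- scale(t(sub))           # cells x genes
    # align refit component signs/order to the original decomposition
    sv0 <- svd(zs, nu = n_pc, nv = n_pc)
    obs_sum <- matrix(0, G, n_pc)
    obs_n <- integer(G)
    null <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
        pick <- sample(G, m)
        zp <- zs
        for (g in pick) zp[, g] <- zp[sample(nrow(zp)), g]
        svp <- svd(zp, nu = 0, nv = n_pc)
        v2 <- svp$v[, seq_len(n_pc), drop = FALSE]^2
        null[[r]] <- v2[pick, , drop = FALSE]
        obs_sum[-pick, ] <- obs_sum[-pick, ] + v2[-pick, , drop = FALSE]
        obs_n[-pick] <- obs_n[-pick] + 1L
    }
    nullmat <- do.call(rbind, null)               # (n_reps*m) x n_pc
    seen <- obs_n > 0L
    obs <- obs_sum[seen, , drop = FALSE] / obs_n[seen]
    sig <- logical(n_pc)
    for (j in seq_len(n_pc)) {
        pg <- vapply(obs[, j], function(o) mean(nullmat[, j] >= o), numeric(1))
        sig[j] <- binom.test(sum(pg < alpha), length(pg), p = alpha,
                             alternative = "greater")$p.value < 0.05
    }
    if (!sig[1]) return(integer())
    seq_len(which.min(c(sig, FALSE)) - 1L)
}

# k nearest neighbors by brute force; fine at the package's working scales
.knn_index <- function(coords, k) {
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Shared-nearest-neighbor graph community clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding coordinates, weights
#' edges by the Jaccard overlap of the two cells' neighbor lists (shared
#' nearest neighbors), and partitions it by modularity-based community
#' detection (Louvain) at the given resolution. Labels are renumbered by
#' decreasing cluster size.
#'
#' @param embedding \linkS4class{Embedding} or cells-by-d coordinate matrix.
#' @param k_neighbors neighbors per cell (must be < number of cells).
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed (community detection is stochastic).
#' @param prune Jaccard weights below this are dropped (default 1/15).
#' @return Integer cluster label per cell, named by cell.
#' @export
graphCluster <- function(embedding, k_neighbors = 20, resolution = 0.8,
                         seed = 1L, prune = 1/15) {
    coords <- if (is(embedding, "Embedding")) embeddingCoords(embedding) else
        embedding
    n <- nrow(coords)
    if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of cells")
    nn <- .knn_index(coords, k_neighbors)
    # Jaccard overlap of kNN lists for each kNN edge
    src <- rep(seq_len(n), each = k_neighbors)
    dst <- as.integer(t(nn))
    w <- numeric(length(src))
    nn_sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
    for (e in seq_along(src)) {
        a <- nn_sets[[src[e]]]; b <- nn_sets[[dst[e]]]
        ov <- length(intersect(a, b))
        w[e] <- ov / (2 * (k_neighbors + 1) - ov)
    }
    keep <- w >= prune & src < dst   # undirected, pruned
    # also keep the reverse-listed edges (src > dst) not seen as src < dst
    keep2 <- w >= prune & src > dst
    ek <- unique(rbind(cbind(pmin(src, dst)[keep | keep2],
                             pmax(src, dst)[keep | keep2])))
    wmap <- tapply(w[keep | keep2],
                   paste(pmin(src, dst)[keep | keep2],
                         pmax(src, dst)[keep | keep2]), max)
    g <- igraph::graph_from_edgelist(ek, directed = FALSE)
    g <- igraph::set_edge_attr(g, "weight",
                               value = as.numeric(wmap[paste(ek[, 1], ek[, 2])]))
    if (igraph::vcount(g) < n)
        g <- igraph::add_vertices(g, n - igraph::vcount(g))
    set.seed(seed)
    cm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- .relabel_by_size(igraph::membership(cm))
    setNames(labels, rownames(coords))
}

#' Best-of-n t-SNE
#'
#' Runs \code{n_runs} randomly initiated t-SNE embeddings and returns the one
#' with the lowest final Kullback-Leibler divergence; all runs' divergences
#' are retained in the result.
#'
#' @param embedding_input \linkS4class{Embedding} or cells-by-d matrix
#'   (typically significant PCs).
#' @param n_runs number of runs (>= 1).
#' @param perplexity t-SNE perplexity; must be < n_cells / 3.
#' @param seed integer seed.
#' @return An \linkS4class{Embedding} with method "tsne";
#'   \code{x@kl_divergence} holds the selected run's KL first, then the rest.
#' @export
tsneBestOf <- function(embedding_input, n_runs = 10, perplexity = 30,
                       seed = 1L) {
    stopifnot(n_runs >= 1)
    coords <- if (is(embedding_input, "Embedding"))
        embeddingCoords(embedding_input) else embedding_input
    if (perplexity >= nrow(coords) / 3)
        stop("perplexity must be below n_cells / 3")
    runs <- vector("list", n_runs)
    kls <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
        set.seed(.substream_seed(seed, paste0("tsne", r)))
        fit <- Rtsne::Rtsne(coords, dims = 2, perplexity = perplexity,
                            pca = FALSE, verbose = FALSE)
        runs[[r]] <- fit$Y
        kls[r] <- fit$itercosts[length(fit$itercosts)]
    }
    best <- which.min(kls)
    out <- runs[[best]]
    rownames(out) <- rownames(coords)
    new("Embedding", coords = out, method = "tsne",
        explained_variance = numeric(),
        kl_divergence = c(kls[best], kls[-best]))
}
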