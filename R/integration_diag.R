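#' Entropy of batch mixing with negative and positive controls
#'
#' Per bootstrap, \code{n_locations} cells are sampled; each contributes the
#' normalized Shannon entropy -sum(p_b log p_b) / log(B) of the batch
#' proportions among its \code{neighborhood_size} nearest neighbors in the
#' embedding, and the bootstrap records the mean over locations. The
#' negative control (no batch effect) recomputes this with uniformly
#' shuffled batch labels; the positive control (structure entirely
#' batch-driven) uses cluster labels as batches.
#'
#' @param embedding cells-by-d coordinate matrix (e.g. t-SNE).
#' @param batch_labels batch per cell (>= 2 batches).
#' @param clusters cluster labels for the positive control (optional; the
#'   positive control is skipped when NULL).
#' @param n_locations,neighborhood_size,n_boot see Details; defaults 100.
#' @param seed integer seed.
#' @return data.frame with one row per bootstrap and columns observed,
#'   negative_control, positive_control (NA when skipped).
#' @export
batchEntropy <- function(embedding, batch_labels, clusters = NULL,
                         n_locations = 100, neighborhood_size = 100,
                         n_boot = 100, seed = 1L) {
    coords <- if (is(embedding, "Embedding")) embeddingCoords(embedding) else
        embedding
    n <- nrow(coords)
    batch_labels <- as.character(batch_labels)
    if (length(unique(batch_labels)) < 2L) stop("need >= 2 batches")
    if (neighborhood_size >= n) {
        warning("neighborhood_size clamped to n_cells - 1")
        neighborhood_size <- n - 1L
    }
    D <- as.matrix(dist(coords))
    diag(D) <- Inf
    nn <- t(apply(D, 1, function(r) order(r)[seq_len(neighborhood_size)]))
    set.seed(seed)
    boot_mean <- function(labels) {
        B <- length(unique(labels))
        locs <- sample(n, n_locations, replace = TRUE)
        mean(vapply(locs, function(i)
            normalizedEntropy(table(labels[nn[i, ]])), numeric(1)))
    }
    out <- data.frame(observed = numeric(n_boot),
                      negative_control = numeric(n_boot),
                      positive_control = NA_real_)
    for (b in seq_len(n_boot)) {
        out$observed[b] <- boot_mean(batch_labels)
        out$negative_control[b] <- boot_mean(sample(batch_labels))
        if (!is.null(clusters))
            out$positive_control[b] <- boot_mean(as.character(clusters))
    }
    out
}

#' Normalized Shannon entropy of label counts
#'
#' -sum(p log p) / log(B) over the proportions of a count vector, with B the
#' number of categories (including zero-count categories when the vector is
#' a named table over all levels). Counts (75, 25) over two categories give
#' 0.8113.
#'
#' @param counts non-negative counts per category.
#' @return Entropy in [0, 1]; 0 when a single category holds everything.
#' @export
normalizedEntropy <- function(counts) {
    B <- length(counts)
    if (B < 2L) return(0)
    p <- counts / sum(counts)
    p <- p[p > 0]
    -sum(p * log(p)) / log(B)
}

#' Pseudo-bulk profiles by group
#'
#' Per-gene mean expression within each group of cells.
#'
#' @param expr genes-by-cells matrix (normalized log expression).
#' @param labels group label per cell (every group >= 1 cell).
#' @return genes-by-groups matrix with group sizes in
#'   \code{attr(, "group_sizes")}.
#' @export
pseudobulk <- function(expr, labels) {
    labels <- as.character(labels)
    ulab <- sort(unique(labels))
    out <- vapply(ulab, function(k)
        rowMeans(expr[, labels == k, drop = FALSE]), numeric(nrow(expr)))
    rownames(out) <- rownames(expr)
    attr(out, "group_sizes") <- table(labels)[ulab]
    out
}

#' Quantile normalization against a reference column
#'
#' Every column's values are replaced rank-wise by the reference column's
#' sorted values; tied ranks map to the mean of the tied reference
#' positions. The reference column itself is unchanged and the transform is
#' idempotent.
#'
#' @param m numeric matrix.
#' @param reference_column name or index of the reference column.
#' @return Matrix of the same shape.
#' @export
quantileNormalizeToReference <- function(m, reference_column) {
    ref <- m[, reference_column]
    if (length(ref) != nrow(m)) stop("reference length mismatch")
    ref_sorted <- sort(ref)
    idx <- seq_len(nrow(m))
    apply(m, 2, function(x) {
        r <- rank(x, ties.method = "average")
        approx(idx, ref_sorted, xout = r)$y
    })
}

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch correction with parametric empirical-Bayes shrinkage
#' of the batch parameters (the ComBat algorithm). A single batch returns
#' the input with a warning.
#'
#' @param m genes-by-samples matrix.
#' @param batch_labels batch per sample (each batch >= 2 samples).
#' @return Corrected matrix.
#' @export
ebBatchAdjust <- function(m, batch_labels) {
    batch_labels <- as.character(batch_labels)
    if (length(unique(batch_labels)) < 2L) {
        warning("single batch; returning input unchanged")
        return(m)
    }
    if (any(table(batch_labels) < 2L))
        stop("every batch needs at least 2 samples")
    # ComBat drops zero-variance genes; keep and restore them
    v <- apply(m, 1, var)
    out <- m
    out[v > 0, ] <- sva::ComBat(dat = m[v > 0, , drop = FALSE],
                                batch = batch_labels)
    out
}

#' Complete-linkage sample tree
#'
#' Euclidean distance on a feature subset, complete-linkage hierarchical
#' clustering of the columns, with optional Newick export.
#'
#' @param m genes-by-samples matrix.
#' @param feature_subset features (rows) to use; default all.
#' @param newick_path optional file to write the tree in Newick format.
#' @return The \code{hclust} object.
#' @export
completeLinkageTree <- function(m, feature_subset = rownames(m),
                                newick_path = NULL) {
    if (ncol(m) < 2L) stop("need at least 2 columns")
    sub <- m[intersect(feature_subset, rownames(m)), , drop = FALSE]
    hc <- hclust(dist(t(sub)), method = "complete")
    if (!is.null(newick_path))
        ape::write.tree(ape::as.phylo(hc), file = newick_path)
    hc
}

#' Cluster-average tree with per-node out-of-bag error
#'
#' Builds a dendrogram over cluster average cells (over the given genes) and,
#' for every internal node, trains a random forest to allocate the node's
#' member cells to its left or right branch; the forest's out-of-bag error
#' is the node's confidence score (low error = well-separated split).
#'
#' @param expr genes-by-cells matrix (typically variable genes).
#' @param labels cluster label per cell (>= 2 clusters).
#' @param ntree trees per node forest (default 500).
#' @param seed integer seed.
#' @return list(tree = hclust over clusters, node_oobe = data.frame(node,
#'   left, right, oob_error)).
#' @export
clusterMeanTree <- function(expr, labels, ntree = 500, seed = 1L) {
    labels <- as.character(labels)
    means <- pseudobulk(expr, labels)
    if (ncol(means) < 2L) stop("need at least 2 clusters")
    hc <- hclust(dist(t(means)), method = "complete")
    merges <- hc$merge
    clusters_of <- function(i) {
        if (i < 0) return(hc$labels[-i])
        c(clusters_of(merges[i, 1]), clusters_of(merges[i, 2]))
    }
    rows <- lapply(seq_len(nrow(merges)), function(nd) {
        left <- clusters_of(merges[nd, 1])
        right <- clusters_of(merges[nd, 2])
        sel <- labels %in% c(left, right)
        side <- factor(ifelse(labels[sel] %in% left, "left", "right"))
        if (min(table(side)) < 2L)
            return(data.frame(node = nd, left = paste(left, collapse = ","),
                              right = paste(right, collapse = ","),
                              oob_error = NA_real_))
        set.seed(.substream_seed(seed, paste0("node", nd)))
        fit <- randomForest::randomForest(x = t(expr[, sel, drop = FALSE]),
                                          y = side, ntree = ntree)
        data.frame(node = nd, left = paste(left, collapse = ","),
                   right = paste(right, collapse = ","),
                   oob_error = unname(fit$err.rate[ntree, "OOB"]))
    })
    list(tree = hc, node_oobe = do.call(rbind, rows))
}

#' Cluster composition by replicate with per-cluster tests
#'
#' Per replicate, each cluster's fraction of that replicate's cells; per
#' cluster, a Welch t-test of the fractions across the two conditions.
#'
#' @param labels cluster label per cell.
#' @param sample_ids replicate id per cell.
#' @param condition condition per cell (2 levels; >= 2 replicates each).
#' @return list(fractions = replicates-by-clusters matrix, table =
#'   data.frame(cluster, mean_A, mean_B, sd_A, sd_B, p_value)).
#' @export
compositionSummary <- function(labels, sample_ids, condition) {
    labels <- as.character(labels)
    sample_ids <- as.character(sample_ids)
    cond_of <- tapply(as.character(condition), sample_ids,
                      function(x) unique(x)[1])
    levs <- unique(as.character(condition))
    if (length(levs) != 2L) stop("need exactly 2 conditions")
    if (any(table(cond_of) < 2L)) stop("need >= 2 replicates per condition")
    ulab <- sort(unique(labels))
    reps <- sort(unique(sample_ids))
    frac <- t(vapply(reps, function(r) {
        sel <- sample_ids == r
        as.numeric(table(factor(labels[sel], levels = ulab)) / sum(sel))
    }, numeric(length(ulab))))
    dimnames(frac) <- list(reps, ulab)
    tab <- do.call(rbind, lapply(ulab, function(k) {
        a <- frac[cond_of[reps] == levs[1], k]
        b <- frac[cond_of[reps] == levs[2], k]
        p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) 1 else
            tryCatch(t.test(a, b)$p.value, error = function(e) 1)
        data.frame(cluster = k, mean_A = mean(a), mean_B = mean(b),
                   sd_A = sd(a), sd_B = sd(b), p_value = p,
                   stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    list(fractions = frac, table = tab)
}
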