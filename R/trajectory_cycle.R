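#' Diffusion map of cells
#'
#' Builds a Gaussian kernel on the (symmetrized) k-nearest-neighbor graph
#' with a per-cell local bandwidth (the distance to a small-quantile
#' neighbor), applies the standard density normalization (alpha = 1) and
#' row-normalizes to a transition operator; its top non-trivial
#' eigenvectors are the diffusion components. With a disconnected graph the
#' map is computed on the largest connected component and the remaining
#' cells are flagged (their coordinates are NA).
#'
#' @param expr genes-by-cells matrix over variable genes (cells are
#'   columns), or a cells-by-d coordinate matrix with
#'   \code{cells_in_rows = TRUE}.
#' @param k_nn neighbors per cell (default 500; clamped with a warning when
#'   >= n_cells).
#' @param n_components non-trivial components to return (default 10).
#' @param cells_in_rows set TRUE when \code{expr} is cells-by-features.
#' @return A \linkS4class{DiffusionResult}.
#' @export
diffusionMap <- function(expr, k_nn = 500, n_components = 10,
                         cells_in_rows = FALSE) {
    X <- if (cells_in_rows) expr else t(expr)
    n <- nrow(X)
    if (k_nn >= n) {
        warning("k_nn >= n_cells; clamped to n_cells - 1")
        k_nn <- n - 1L
    }
    D <- as.matrix(dist(X))
    diag(D) <- Inf
    nn_idx <- t(apply(D, 1, function(r) order(r)[seq_len(k_nn)]))
    # local bandwidth: distance to the ceil(k_nn/100)-th neighbor, min the 5th
    bw_rank <- min(max(5L, ceiling(k_nn / 100)), k_nn)
    sigma <- vapply(seq_len(n), function(i) D[i, nn_idx[i, bw_rank]],
                    numeric(1))
    sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
        j <- nn_idx[i, ]
        W[i, j] <- exp(-D[i, j]^2 / (2 * sigma[i] * sigma[j]))
    }
    W <- pmax(W, t(W))   # symmetrize the kNN kernel
    diag(W) <- 1

    # connected components of the kernel graph
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
    in_main <- comp$membership == which.max(comp$csize)
    if (!all(in_main))
        warning(sum(!in_main), " cells outside the largest kNN component ",
                "are flagged and get NA coordinates")
    Wm <- W[in_main, in_main, drop = FALSE]
    nm <- nrow(Wm)

    # density normalization (alpha = 1), then symmetric conjugate of the
    # row-normalized operator
    q <- rowSums(Wm)
    Wt <- Wm / (q %o% q)
    d <- rowSums(Wt)
    S <- Wt / sqrt(d %o% d)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    n_components <- min(n_components, nm - 1L)
    lam <- es$values[2:(n_components + 1L)]
    psi <- es$vectors[, 2:(n_components + 1L), drop = FALSE] / sqrt(d)
    # deterministic sign: largest-magnitude entry positive
    for (j in seq_len(ncol(psi))) {
        i <- which.max(abs(psi[, j]))
        if (psi[i, j] < 0) psi[, j] <- -psi[, j]
    }
    comps <- matrix(NA_real_, n, n_components,
                    dimnames = list(rownames(X),
                                    paste0("DC", seq_len(n_components))))
    comps[in_main, ] <- psi
    new("DiffusionResult",
        eigenvalues = lam,
        components = comps,
        pseudotime = rep(NA_real_, n),
        root_cell = "",
        in_largest_component = setNames(in_main, rownames(X)),
        params = list(k_nn = k_nn, sigma = "local", bw_rank = bw_rank))
}

#' Diffusion pseudotime from a root cell
#'
#' Distance between cells in the space of diffusion components scaled by
#' lambda / (1 - lambda); pseudotime is this distance from the root cell
#' (0 at the root). Components with eigenvalue 1 are excluded from the
#' scaling.
#'
#' @param dmap a \linkS4class{DiffusionResult}.
#' @param root_cell cell name or index.
#' @return The \code{dmap} with pseudotime filled in.
#' @export
diffusionPseudotime <- function(dmap, root_cell) {
    comps <- dmap@components
    if (is.character(root_cell)) {
        ri <- match(root_cell, rownames(comps))
        if (is.na(ri)) stop("root cell '", root_cell, "' not in dataset")
    } else ri <- as.integer(root_cell)
    lam <- dmap@eigenvalues
    usable <- lam < 1
    scale <- lam[usable] / (1 - lam[usable])
    Z <- sweep(comps[, usable, drop = FALSE], 2, scale, "*")
    dpt <- sqrt(rowSums((Z - matrix(Z[ri, ], nrow(Z), ncol(Z),
                                    byrow = TRUE))^2))
    dmap@pseudotime <- setNames(dpt, rownames(comps))
    dmap@root_cell <- as.character(
        if (is.null(rownames(comps))) ri else rownames(comps)[ri])
    dmap
}

#' Train phase-specific marker gene pairs
#'
#' A pair (g_hi, g_lo) is kept for a phase when g_hi exceeds g_lo in at
#' least \code{consistency} of that phase's cells and at most
#' 1 - \code{consistency} of the remaining cells.
#'
#' @param counts genes-by-cells matrix of a phase-annotated reference.
#' @param phase_labels phase per cell; at least 2 phases with >= 20 cells.
#' @param consistency within/outside consistency threshold (default 0.7).
#' @param max_candidate_genes pairs are searched among the genes most
#'   variable across phase means (search is quadratic in this number).
#' @return Named list (one element per phase) of two-column (hi, lo)
#'   character matrices, deduplicated.
#' @export
trainCyclePairs <- function(counts, phase_labels, consistency = 0.7,
                            max_candidate_genes = 60) {
    m <- .as_dense(.get_counts(counts))
    phase_labels <- as.character(phase_labels)
    tab <- table(phase_labels)
    if (sum(tab >= 20) < 2) stop("need >= 2 phases with >= 20 cells")
    pm <- vapply(names(tab), function(p)
        rowMeans(m[, phase_labels == p, drop = FALSE]), numeric(nrow(m)))
    spread <- apply(pm, 1, function(r) max(r) - min(r))
    cand <- order(spread, decreasing = TRUE)[
        seq_len(min(max_candidate_genes, nrow(m)))]
    pairs <- list()
    for (p in names(tab)) {
        inp <- phase_labels == p
        keep <- list()
        for (a in cand) for (b in cand) {
            if (a == b) next
            gt <- m[a, ] > m[b, ]
            if (mean(gt[inp]) >= consistency &&
                mean(gt[!inp]) <= 1 - consistency)
                keep[[length(keep) + 1L]] <- c(rownames(m)[a], rownames(m)[b])
        }
        if (length(keep)) {
            mat <- unique(do.call(rbind, keep))
            colnames(mat) <- c("hi", "lo")
            pairs[[p]] <- mat
        }
    }
    if (!length(pairs))
        stop("no qualifying gene pairs; consider lowering 'consistency'")
    pairs
}

#' Score cells with cell-cycle gene pairs
#'
#' Per cell, the G1 and G2M scores are the fraction of each phase's pairs
#' with strictly higher expression of the pair's hi gene (tied pairs are
#' excluded from the denominator). Phase calls: G1 when g1 >= 0.5 and
#' g2m < 0.5; G2M when g2m >= 0.5 and g1 < 0.5; S otherwise. A cell with
#' all pairs tied in a phase gets an NA score and falls back to S.
#'
#' @param counts genes-by-cells matrix.
#' @param pairs named list of (hi, lo) pair matrices, as from
#'   \code{\link{trainCyclePairs}}; must contain "G1" and "G2M".
#' @return data.frame: barcode, g1_score, g2m_score, phase.
#' @export
scoreCycle <- function(counts, pairs) {
    m <- .as_dense(.get_counts(counts))
    score_one <- function(pp) {
        pp <- pp[pp[, 1] %in% rownames(m) & pp[, 2] %in% rownames(m), ,
                 drop = FALSE]
        if (!nrow(pp)) stop("no scored pair genes present in the matrix")
        hi <- m[pp[, 1], , drop = FALSE]
        lo <- m[pp[, 2], , drop = FALSE]
        wins <- colSums(hi > lo)
        ties <- colSums(hi == lo)
        denom <- nrow(pp) - ties
        ifelse(denom > 0, wins / denom, NA_real_)
    }
    g1 <- score_one(pairs[["G1"]])
    g2m <- score_one(pairs[["G2M"]])
    phase <- ifelse(!is.na(g1) & !is.na(g2m) & g1 >= 0.5 & g2m < 0.5, "G1",
             ifelse(!is.na(g1) & !is.na(g2m) & g2m >= 0.5 & g1 < 0.5, "G2M",
                    "S"))
    data.frame(barcode = colnames(m), g1_score = g1, g2m_score = g2m,
               phase = phase, row.names = colnames(m),
               stringsAsFactors = FALSE)
}

#' G2M proportion by cluster
#'
#' Fraction of cells called G2M within each cluster, sorted decreasing — the
#' proliferative clusters rank first.
#'
#' @param phase phase call per cell.
#' @param clusters cluster label per cell.
#' @return Named numeric vector of G2M proportions per cluster.
#' @export
g2mProportionByCluster <- function(phase, clusters) {
    sort(tapply(phase == "G2M", as.character(clusters), mean),
         decreasing = TRUE)
}
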