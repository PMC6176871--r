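#' Rank cluster markers by classifier AUC
#'
#' For each gene, the target cluster is the cluster with the highest mean
#' expression; the gene's power to distinguish that cluster's cells from all
#' others is quantified as the area under the ROC curve (rank-sum with
#' midranks, ties count one half). Per cluster, genes are ranked by AUC and
#' the top \code{top_n} retained as candidate markers.
#'
#' @param expr genes-by-cells expression matrix.
#' @param labels cluster label per cell (>= 2 clusters).
#' @param top_n candidates kept per cluster (default 200).
#' @return Marker data.frame: gene, cluster, auc, pct_in, pct_out, log_fc
#'   (natural log of cluster-mean ratios on the de-logged scale), flagged
#'   when the target cluster has a single cell.
#' @export
aucMarkers <- function(expr, labels, top_n = 200) {
    labels <- as.character(labels)
    ulab <- unique(labels)
    if (length(ulab) < 2L) stop("need at least 2 clusters")
    gm <- vapply(ulab, function(k)
        rowMeans(expr[, labels == k, drop = FALSE]), numeric(nrow(expr)))
    target <- ulab[max.col(gm)]
    rows <- lapply(seq_len(nrow(expr)), function(i) {
        k <- target[i]
        pos <- labels == k
        x <- expr[i, ]
        data.frame(gene = rownames(expr)[i], cluster = k,
                   auc = aucRank(x, pos),
                   pct_in = mean(x[pos] > 0), pct_out = mean(x[!pos] > 0),
                   log_fc = .lnfc(x, pos),
                   singleton_cluster = sum(pos) == 1L,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$cluster), function(ix) {
        ix[order(-tab$auc[ix])][seq_len(min(top_n, length(ix)))]
    }))
    out <- tab[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# natural-log fold change of group means on the de-logged expression scale
.lnfc <- function(x, pos) {
    m1 <- mean(2^x[pos] - 1)
    m0 <- mean(2^x[!pos] - 1)
    log((m1 + 1) / (m0 + 1))
}

#' Filtered marker tests for one or all clusters
#'
#' Genes are tested only when detected in at least \code{min_pct} of cells
#' in either group and when the absolute log fold change reaches
#' \code{logfc_threshold}. In \code{test = "auc"} mode, genes are reported
#' when their discriminative power |AUC - 0.5| is at least
#' \code{0.5 - return_thresh} (i.e. AUC outside
#' [\code{return_thresh}, 1 - \code{return_thresh}]). In
#' \code{test = "negbinom"} mode the filtered genes are passed to
#' \code{\link{nbGlmDe}}.
#'
#' @param expr genes-by-cells log2 expression matrix.
#' @param labels cluster label per cell.
#' @param cluster cluster to test against the rest; NULL tests every cluster.
#' @param min_pct minimum detection fraction in either group (default 0.25).
#' @param logfc_threshold minimum |ln fold change| (default 0.25).
#' @param return_thresh AUC reporting threshold (default 0.3).
#' @param test "auc" or "negbinom".
#' @param counts,size_factors,latent passed to \code{\link{nbGlmDe}} when
#'   \code{test = "negbinom"}.
#' @return Marker data.frame (possibly empty).
#' @export
filteredMarkers <- function(expr, labels, cluster = NULL, min_pct = 0.25,
                            logfc_threshold = 0.25, return_thresh = 0.3,
                            test = c("auc", "negbinom"), counts = NULL,
                            size_factors = NULL, latent = NULL) {
    test <- match.arg(test)
    labels <- as.character(labels)
    todo <- if (is.null(cluster)) unique(labels) else as.character(cluster)
    out <- list()
    for (k in todo) {
        pos <- labels == k
        pct_in <- rowMeans(expr[, pos, drop = FALSE] > 0)
        pct_out <- rowMeans(expr[, !pos, drop = FALSE] > 0)
        lfc <- vapply(seq_len(nrow(expr)),
                      function(i) .lnfc(expr[i, ], pos), numeric(1))
        testable <- (pmax(pct_in, pct_out) >= min_pct) &
            (abs(lfc) >= logfc_threshold)
        if (!any(testable)) next
        genes <- rownames(expr)[testable]
        if (test == "auc") {
            auc <- vapply(genes, function(g) aucRank(expr[g, ], pos),
                          numeric(1))
            sel <- abs(auc - 0.5) >= (0.5 - return_thresh)
            if (!any(sel)) next
            out[[k]] <- data.frame(
                gene = genes[sel], cluster = k, auc = auc[sel],
                pct_in = pct_in[testable][sel],
                pct_out = pct_out[testable][sel],
                log_fc = lfc[testable][sel],
                p_value = NA_real_, p_adj = NA_real_,
                stringsAsFactors = FALSE)
        } else {
            de <- nbGlmDe(counts[genes, , drop = FALSE],
                          group = factor(ifelse(pos, "in", "out"),
                                         levels = c("out", "in")),
                          latent = latent, size_factors = size_factors)
            de$cluster <- k
            de$pct_in <- pct_in[testable]
            de$pct_out <- pct_out[testable]
            out[[k]] <- de
        }
    }
    if (!length(out))
        return(data.frame(gene = character(), cluster = character(),
                          auc = numeric(), pct_in = numeric(),
                          pct_out = numeric(), log_fc = numeric(),
                          p_value = numeric(), p_adj = numeric()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# method-of-moments NB dispersion with one Newton refinement on the
# pseudo-likelihood equation sum((y-mu)^2/(mu+phi*mu^2)) = n - p
.estimate_phi <- function(y, mu, p) {
    n <- length(y)
    num <- sum((y - mu)^2 / mu^2) - sum(1 / mu)
    den <- n - p
    phi <- max(num / den, 0)
    if (phi > 0) {
        f <- function(ph) sum((y - mu)^2 / (mu + ph * mu^2)) - (n - p)
        fp <- function(ph) -sum((y - mu)^2 * mu^2 / (mu + ph * mu^2)^2)
        step <- f(phi) / fp(phi)
        if (is.finite(step)) phi <- max(phi - step, 0)
    }
    phi
}

#' Negative-binomial differential expression with latent covariates
#'
#' Per gene, fits a negative-binomial log-linear model of counts on the
#' group factor plus latent covariates (e.g. total UMIs, cycle scores,
#' batch) with a log size-factor offset. The dispersion is estimated by
#' method of moments from a Poisson fit and refined by one Newton step,
#' then the group coefficient is tested by a Wald test; p-values are
#' BH-adjusted. All-zero genes are excluded; non-converging fits are
#' flagged with NA p-values.
#'
#' @param counts genes-by-cells integer counts.
#' @param group two-level factor per cell (test is on its second level).
#' @param latent optional data.frame of per-cell covariates.
#' @param size_factors per-cell positive factors (default library size,
#'   scaled to mean 1).
#' @return data.frame: gene, log_fc (natural log, group effect), log2_fc,
#'   phi, p_value, p_adj.
#' @export
nbGlmDe <- function(counts, group, latent = NULL, size_factors = NULL) {
    m <- .as_dense(.get_counts(counts))
    group <- droplevels(as.factor(group))
    stopifnot(nlevels(group) == 2L, all(table(group) > 0))
    if (is.null(size_factors)) {
        lib <- colSums(m)
        size_factors <- lib / mean(lib)
    }
    off <- log(size_factors)
    dat <- data.frame(group = group)
    if (!is.null(latent)) dat <- cbind(dat, as.data.frame(latent))
    X <- model.matrix(~ ., data = dat)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        warning("dropping collinear latent columns")
        X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
    gcol <- grep("^group", colnames(X))[1]

    res <- lapply(seq_len(nrow(m)), function(i) {
        y <- m[i, ]
        if (all(y == 0)) return(NULL)
        fit0 <- tryCatch(
            glm.fit(X, y, family = poisson(), offset = off),
            error = function(e) NULL)
        if (is.null(fit0) || !fit0$converged)
            return(data.frame(gene = rownames(m)[i], log_fc = NA_real_,
                              log2_fc = NA_real_, phi = NA_real_,
                              p_value = NA_real_))
        phi <- .estimate_phi(y, pmax(fit0$fitted.values, 1e-8), ncol(X))
        fit <- if (phi > 1e-8) {
            fam <- MASS::negative.binomial(theta = 1 / phi)
            tryCatch(glm.fit(X, y, family = fam, offset = off,
                             mustart = pmax(fit0$fitted.values, 1e-4)),
                     error = function(e) NULL)
        } else fit0
        if (is.null(fit) || !fit$converged || fit$rank < ncol(X))
            return(data.frame(gene = rownames(m)[i], log_fc = NA_real_,
                              log2_fc = NA_real_, phi = phi,
                              p_value = NA_real_))
        b <- coef(fit)[gcol]
        # Wald SE from the weighted information matrix
        w <- fit$weights
        XtWX <- crossprod(X * sqrt(w))
        se <- tryCatch(sqrt(diag(solve(XtWX)))[gcol],
                       error = function(e) NA_real_)
        p <- if (is.na(se) || se == 0) NA_real_ else
            2 * pnorm(-abs(b / se))
        data.frame(gene = rownames(m)[i], log_fc = b, log2_fc = b / log(2),
                   phi = phi, p_value = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) return(data.frame(gene = character(),
                                        log_fc = numeric(),
                                        log2_fc = numeric(), phi = numeric(),
                                        p_value = numeric(),
                                        p_adj = numeric()))
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    rownames(out) <- NULL
    out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set, against a background universe of expressed genes;
#' p-values are BH-adjusted and sets significant at the given FDR flagged.
#'
#' @param query character vector of query genes (subset of background).
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param background character vector, the expressed-gene universe.
#' @param fdr significance threshold (default 0.05).
#' @return data.frame: set, overlap, set_size, query_size, p_value, p_adj,
#'   significant.
#' @export
genesetEnrichment <- function(query, gene_sets, background, fdr = 0.05) {
    if (!length(background)) stop("empty background universe")
    query <- intersect(query, background)
    N <- length(background)
    rows <- lapply(names(gene_sets), function(s) {
        set <- intersect(gene_sets[[s]], background)
        ov <- length(intersect(query, set))
        p <- phyper(ov - 1, length(set), N - length(set), length(query),
                    lower.tail = FALSE)
        data.frame(set = s, overlap = ov, set_size = length(set),
                   query_size = length(query), p_value = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_value < fdr & out$p_adj < fdr
    rownames(out) <- NULL
    out
}

#' Cross-tabulate marker-set overlaps between two clusterings
#'
#' For every pair of clusters (one from each marker collection), counts the
#' shared marker genes and tests enrichment of the overlap by a one-sided
#' Fisher exact test over the universe.
#'
#' @param markers_A,markers_B named lists of per-cluster marker gene sets.
#' @param universe character vector of background genes.
#' @return list(shared = count matrix, p = p-value matrix,
#'   neg_log10_p = display matrix), rows = clusters of A, columns = of B.
#' @export
markerOverlapTable <- function(markers_A, markers_B, universe) {
    if (!length(universe)) stop("empty universe")
    nA <- length(markers_A); nB <- length(markers_B)
    shared <- p <- matrix(NA_real_, nA, nB,
                          dimnames = list(names(markers_A), names(markers_B)))
    for (i in seq_len(nA)) for (j in seq_len(nB)) {
        a <- intersect(markers_A[[i]], universe)
        b <- intersect(markers_B[[j]], universe)
        ov <- length(intersect(a, b))
        tab <- matrix(c(ov, length(a) - ov, length(b) - ov,
                        length(universe) - length(a) - length(b) + ov), 2, 2)
        shared[i, j] <- ov
        p[i, j] <- fisher.test(tab, alternative = "greater")$p.value
    }
    list(shared = shared, p = p, neg_log10_p = -log10(p))
}
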