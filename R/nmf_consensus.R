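#' @useDynLib stromatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# one KL-NMF factorization from a random initialization
.nmf_once <- function(V, k, max_iter = 2000, tol = 1e-6) {
    m <- nrow(V); n <- ncol(V)
    W <- matrix(runif(m * k, 1e-3, 1), m, k)
    H <- matrix(runif(k * n, 1e-3, 1), k, n)
    .nmf_kl_cpp(V, W, H, as.integer(max_iter), tol)
}

#' NMF consensus clustering of cells with rank survey
#'
#' For every rank in \code{rank_range}, runs \code{n_runs} randomly
#' initiated non-negative matrix factorizations (Kullback-Leibler objective,
#' multiplicative updates) of the non-negative expression matrix; each run
#' assigns every cell to its arg-max basis component, and the consensus
#' matrix records the fraction of runs in which each cell pair is
#' co-assigned (1 = always together, 0 = never). Per rank it reports the
#' cophenetic correlation of the consensus dendrogram, the average
#' silhouette width on 1 - consensus, the dispersion mean(4 (c - 1/2)^2),
#' and the residual sum of squares of the best-objective fit. The rank is
#' then chosen by \code{\link{rankSelect}} and cell labels derived by an
#' average-linkage cut of 1 - consensus into that many groups.
#'
#' @param expr_modules non-negative genes-by-cells matrix (module genes).
#' @param rank_range integer ranks to survey (within [2, n_cells - 1]).
#' @param n_runs random restarts per rank (default 50).
#' @param seed integer seed.
#' @param control_metrics optional metrics data.frame from a permuted-data
#'   run, stored alongside.
#' @param max_iter,tol stopping rule of the multiplicative updates.
#' @return A \linkS4class{ConsensusClustering}.
#' @export
nmfConsensus <- function(expr_modules, rank_range = 2:8, n_runs = 50,
                         seed = 1L, control_metrics = data.frame(),
                         max_iter = 2000, tol = 1e-6) {
    V <- .as_dense(expr_modules)
    if (nrow(V) < 2L || ncol(V) < 3L) stop("NMF input is degenerate")
    if (any(V < 0)) stop("NMF input must be non-negative")
    n <- ncol(V)
    stopifnot(all(rank_range >= 2), all(rank_range <= n - 1))
    consensus <- vector("list", length(rank_range))
    metrics <- data.frame(rank = rank_range, cophenetic = NA_real_,
                          silhouette = NA_real_, dispersion = NA_real_,
                          rss = NA_real_)
    for (ri in seq_along(rank_range)) {
        k <- rank_range[ri]
        set.seed(.substream_seed(seed, paste0("nmf", k)))
        co <- matrix(0, n, n)
        best_kl <- Inf; best_WH <- NULL
        for (r in seq_len(n_runs)) {
            fit <- .nmf_once(V, k, max_iter, tol)
            lab <- max.col(t(fit$H))
            co <- co + outer(lab, lab, "==")
            if (fit$kl < best_kl) {
                best_kl <- fit$kl
                best_WH <- fit$W %*% fit$H
            }
        }
        C <- co / n_runs
        dimnames(C) <- list(colnames(V), colnames(V))
        consensus[[ri]] <- C
        metrics[ri, -1] <- c(.consensus_metrics(C, k),
                             rss = sum((V - best_WH)^2))
    }
    chosen <- if (length(rank_range) >= 3) {
        rankSelect(metrics, control_metrics)
    } else {
        # too few ranks for a peak search: take the most stable consensus
        as.integer(rank_range[which.max(metrics$cophenetic)])
    }
    Cc <- consensus[[match(chosen, rank_range)]]
    labels <- .relabel_by_size(
        cutree(hclust(as.dist(1 - Cc), method = "average"), k = chosen))
    new("ConsensusClustering",
        rank_range = as.integer(rank_range),
        consensus = consensus,
        metrics = metrics,
        control_metrics = control_metrics,
        chosen_rank = as.integer(chosen),
        labels = setNames(as.integer(labels), colnames(V)))
}

# cophenetic correlation, mean silhouette width and dispersion of a
# consensus matrix
.consensus_metrics <- function(C, k) {
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    cop <- suppressWarnings(cor(cophenetic(hc), d))
    if (is.na(cop)) cop <- 1  # zero-variance distances: perfect consensus
    lab <- cutree(hc, k = k)
    sil <- if (length(unique(lab)) > 1) {
        mean(cluster::silhouette(lab, dmatrix = 1 - C)[, "sil_width"])
    } else NA_real_
    disp <- mean(4 * (C - 0.5)^2)
    c(cophenetic = cop, silhouette = sil, dispersion = disp)
}

# interior positions (ascending rank order) that are local maxima of a
# metric vector; the surveyed boundaries are not peaks
.local_maxima <- function(x) {
    n <- length(x)
    if (n < 3L) return(integer())
    cand <- 2:(n - 1)
    cand[x[cand] >= x[cand - 1] & x[cand] > x[cand + 1]]
}

#' Choose the factorization rank from consensus metrics
#'
#' The chosen rank is the smallest rank that is a simultaneous local maximum
#' of cophenetic correlation, silhouette width and dispersion (interior to
#' the surveyed range; the boundaries are not peaks). When no rank
#' satisfies all three, the candidate set falls back to per-metric first
#' local maxima with ties broken toward the RSS inflection point (largest
#' absolute second difference); with no local maximum at all, the smallest
#' surveyed rank is returned with a warning. Metrics of a permuted-data
#' control, when provided, are reported alongside for comparison.
#'
#' @param metrics data.frame with columns rank, cophenetic, silhouette,
#'   dispersion, rss over at least 3 ranks.
#' @param control_metrics optional permuted-control metrics (reported, not
#'   used in the decision).
#' @return The chosen rank (integer).
#' @export
rankSelect <- function(metrics, control_metrics = data.frame()) {
    stopifnot(nrow(metrics) >= 3)
    ranks <- metrics$rank
    lm_c <- .local_maxima(metrics$cophenetic)
    lm_s <- .local_maxima(metrics$silhouette)
    lm_d <- .local_maxima(metrics$dispersion)
    joint <- Reduce(intersect, list(lm_c, lm_s, lm_d))
    if (length(joint)) return(as.integer(ranks[min(joint)]))
    cand <- unique(c(head(lm_c, 1), head(lm_s, 1), head(lm_d, 1)))
    if (!length(cand)) {
        warning("no local maximum in any consensus metric; ",
                "returning the smallest surveyed rank")
        return(as.integer(min(ranks)))
    }
    if (length(cand) == 1L) return(as.integer(ranks[cand]))
    # tie-break toward the RSS inflection (largest |second difference|)
    d2 <- abs(diff(metrics$rss, differences = 2))
    inflect <- which.max(d2) + 1L
    as.integer(ranks[cand[which.min(abs(cand - inflect))]])
}
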