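#' Pooled (deconvolution) size factors
#'
#' Cell-based scaling factors by summing cells into overlapping pools over a
#' ring of cells ordered by library size and deconvolving pool-vs-reference
#' ratios by least squares (the scran deconvolution estimator). Factors are
#' normalized to unit mean. Falls back to library-size factors, with a
#' warning, when there are too few cells for the smallest pool or when the
#' deconvolution returns non-positive estimates.
#'
#' @param counts SingleCellExperiment or genes-by-cells count matrix.
#' @param pool_sizes pool sizes used by the deconvolution.
#' @param clusters optional labels for within-cluster deconvolution.
#' @return Named positive numeric vector of per-cell factors, mean 1.
#' @export
pooledSizeFactors <- function(counts, pool_sizes = c(21, 26, 31, 36, 41),
                              clusters = NULL) {
    m <- .get_counts(counts)
    lib <- .col_totals(m)
    libfac <- lib / mean(lib)
    if (ncol(m) < min(pool_sizes)) {
        warning("fewer cells than the smallest pool; using library-size factors")
        return(setNames(libfac, colnames(m)))
    }
    sf <- tryCatch(
        scran::calculateSumFactors(m, sizes = pool_sizes, clusters = clusters,
                                   positive = TRUE),
        error = function(e) {
            warning("deconvolution failed (", conditionMessage(e),
                    "); using library-size factors")
            libfac
        })
    if (any(sf <= 0)) {
        warning(sum(sf <= 0), " non-positive size factors replaced by ",
                "library-size factors")
        sf[sf <= 0] <- libfac[sf <= 0]
    }
    sf <- sf / mean(sf)
    setNames(as.numeric(sf), colnames(m))
}

#' Log-normalize counts
#'
#' value = log2(count / factor + 1): scaling-factor normalization followed by
#' a variance-stabilizing log2 transform with an offset of 1.
#'
#' @param counts SingleCellExperiment or genes-by-cells count matrix.
#' @param factors positive per-cell size factors.
#' @return Dense genes-by-cells matrix of log2 expression values.
#' @export
logNormalize <- function(counts, factors) {
    m <- .as_dense(.get_counts(counts))
    stopifnot(all(factors > 0), length(factors) == ncol(m))
    log2(sweep(m, 2, factors, "/") + 1)
}

#' Identify in-silico technical control genes from the mean-variance trend
#'
#' Fits a loess trend of per-gene total variance against mean log expression;
#' genes with variance strictly below their fitted value are taken to show
#' only technical variability and returned as control genes.
#'
#' @param expr genes-by-cells log-expression matrix (>= 100 genes).
#' @param span loess span.
#' @return list(trend = data.frame(mean, variance, fitted),
#'   control_genes = character vector).
#' @export
selectControlGenes <- function(expr, span = 0.3) {
    if (nrow(expr) < 100L) stop("need at least 100 genes to fit a trend")
    mu <- rowMeans(expr)
    v <- apply(expr, 1, var)
    if (all(v == 0)) {
        warning("expression matrix is constant; no control genes")
        return(list(trend = data.frame(mean = mu, variance = v, fitted = 0),
                    control_genes = character()))
    }
    fit <- loess(v ~ mu, span = span, degree = 2)
    fitted <- predict(fit, mu)
    ctrl <- rownames(expr)[!is.na(fitted) & v < fitted]
    list(trend = data.frame(mean = mu, variance = v, fitted = fitted,
                            row.names = rownames(expr)),
         control_genes = ctrl)
}

#' Remove unwanted variation estimated from control genes
#'
#' Estimates \code{k_unwanted} factors of unwanted variation as the leading
#' singular vectors (over cells) of the row-centered control-gene submatrix
#' and regresses their contribution out of every gene, RUVg-style. With
#' \code{k_unwanted = 0} the input is returned unchanged.
#'
#' @param expr genes-by-cells log-expression matrix.
#' @param control_genes character vector of control gene names.
#' @param k_unwanted number of unwanted factors (default 1).
#' @return Adjusted matrix of the same shape.
#' @export
ruvRemove <- function(expr, control_genes, k_unwanted = 1) {
    if (k_unwanted == 0) return(expr)
    control_genes <- intersect(control_genes, rownames(expr))
    if (length(control_genes) < k_unwanted)
        stop("fewer control genes than unwanted factors")
    ec <- expr[control_genes, , drop = FALSE]
    ec <- ec - rowMeans(ec)
    if (all(abs(ec) < 1e-12))
        stop("control genes are constant; unwanted factors are undefined")
    sv <- svd(ec, nu = 0, nv = k_unwanted)
    W <- sv$v[, seq_len(k_unwanted), drop = FALSE]   # cells x k, orthonormal
    # project every row-centered gene onto the unwanted factors and subtract;
    # gene means are preserved
    mu <- rowMeans(expr)
    e0 <- expr - mu
    e0 - (e0 %*% W) %*% t(W) + mu
}

#' Regress per-cell covariates out of expression
#'
#' Per-gene least squares on an intercept plus the given covariates
#' (categorical columns are one-hot encoded); returns residuals plus the gene
#' mean, so the location of each gene is preserved. Collinear columns are
#' dropped with a warning.
#'
#' @param expr genes-by-cells matrix.
#' @param covariates data.frame of per-cell covariates (e.g. total UMIs,
#'   batch, cycle scores).
#' @return Adjusted matrix of the same shape.
#' @export
regressOut <- function(expr, covariates) {
    stopifnot(nrow(covariates) == ncol(expr))
    X <- model.matrix(~ ., data = as.data.frame(covariates))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
        warning("dropping collinear covariate columns: ",
                paste(drop, collapse = ", "))
        X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
        qx <- qr(X)
    }
    resid <- t(qr.resid(qx, t(expr)))
    resid + rowMeans(expr)
}

#' Select variable genes by mean/SD thresholds
#'
#' Genes detected in fewer than \code{min_cells} cells are removed first;
#' the remaining genes are kept when the mean of their non-zero values lies
#' strictly between \code{mean_low} and \code{mean_high} and their standard
#' deviation over all cells exceeds \code{sd_min}.
#'
#' @param expr genes-by-cells log-expression matrix.
#' @param mean_low,mean_high bounds on the mean of non-zero values
#'   (defaults 0.0125 and 4).
#' @param sd_min minimum standard deviation over all cells (default 0.5).
#' @param min_cells minimum number of cells detecting the gene (default 3).
#' @return Character vector of selected gene names.
#' @export
selectVariableGenes <- function(expr, mean_low = 0.0125, mean_high = 4,
                                sd_min = 0.5, min_cells = 3) {
    stopifnot(mean_low < mean_high)
    det <- rowSums(expr > 0)
    keep <- det >= min_cells
    nzmean <- vapply(seq_len(nrow(expr)), function(i) {
        x <- expr[i, ]
        x <- x[x > 0]
        if (length(x)) mean(x) else 0
    }, numeric(1))
    sds <- apply(expr, 1, sd)
    sel <- keep & nzmean > mean_low & nzmean < mean_high & sds > sd_min
    rownames(expr)[sel]
}
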