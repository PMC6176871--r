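#' Call cell-containing barcodes from the UMI total distribution
#'
#' Barcodes with fewer than \code{min_umi_floor} UMIs (250 by default) are
#' removed first. A Gaussian kernel density of log10 total UMIs is then
#' estimated on the remainder over a 512-point grid; the calling threshold is
#' the first local minimum of the density scanning from low to high totals —
#' the valley between the ambient and cell modes of the bimodal barcode
#' distribution. Barcodes above the threshold are called cells. If no
#' interior local minimum exists (unimodal density), the floor is used with
#' a warning.
#'
#' @param counts SingleCellExperiment or genes-by-barcodes count matrix.
#' @param min_umi_floor hard minimum UMI count (default 250).
#' @param kde_bandwidth numeric bandwidth for the log10 density, or "auto"
#'   for Silverman's rule of thumb.
#' @return list(threshold = UMI threshold on the count scale,
#'   is_cell = named logical per barcode, density = the density object).
#' @export
callCells <- function(counts, min_umi_floor = 250, kde_bandwidth = "auto") {
    totals <- .col_totals(.get_counts(counts))
    keep <- totals >= min_umi_floor
    if (sum(keep) < 2L) {
        if (any(keep)) warning("fewer than 2 barcodes above the floor; ",
                               "using the floor as threshold")
        return(list(threshold = min_umi_floor,
                    is_cell = setNames(keep, names(totals)),
                    density = NULL))
    }
    x <- log10(totals[keep])
    bw <- if (identical(kde_bandwidth, "auto")) stats::bw.nrd0(x) else
        kde_bandwidth
    d <- density(x, bw = bw, n = 512)
    y <- d$y
    # interior grid points strictly below both neighbors, scanning from low
    # to high; a candidate counts as the inter-mode valley only when (a) the
    # density rises to at least twice its depth on both sides (screens out
    # sampling wiggles of a single mode) and (b) a substantive fraction of
    # above-floor barcodes sits above it (the cell mode is a real mode, not
    # an outlier bump)
    lo <- which(y[2:511] < y[1:510] & y[2:511] < y[3:512]) + 1L
    lo <- lo[vapply(lo, function(i)
        max(y[1:(i - 1)]) >= 2 * y[i] && max(y[(i + 1):512]) >= 2 * y[i] &&
            mean(x > d$x[i]) >= 0.05,
        logical(1))]
    if (length(lo)) {
        threshold <- 10^d$x[lo[1]]
    } else {
        warning("UMI density is unimodal; falling back to the floor threshold")
        threshold <- min_umi_floor
    }
    threshold <- max(threshold, min_umi_floor)
    list(threshold = threshold,
         is_cell = setNames(totals > threshold, names(totals)),
         density = d)
}

#' Compute per-cell QC metrics
#'
#' @param counts SingleCellExperiment or genes-by-cells count matrix.
#' @param mito_prefix prefix of mitochondrial gene names.
#' @return data.frame with barcode, total_umis, n_genes_detected, pct_mito
#'   (percent, 0-100).
#' @export
cellMetrics <- function(counts, mito_prefix = "MT-") {
    m <- .get_counts(counts)
    totals <- .col_totals(m)
    ngenes <- if (is(m, "Matrix")) Matrix::colSums(m > 0) else colSums(m > 0)
    mito <- startsWith(rownames(m), mito_prefix)
    mito_tot <- if (any(mito)) .col_totals(m[mito, , drop = FALSE]) else
        rep(0, ncol(m))
    data.frame(barcode = colnames(m), total_umis = as.integer(totals),
               n_genes_detected = as.integer(ngenes),
               pct_mito = ifelse(totals > 0, 100 * mito_tot / totals, 0),
               row.names = colnames(m), stringsAsFactors = FALSE)
}

#' Filter cells on mitochondrial content
#'
#' Removes cells whose mitochondrial UMI percentage strictly exceeds
#' \code{mito_max_pct} (5\% by default; a cell at exactly the threshold is
#' retained). The returned cell table carries totals, genes detected and
#' percent mitochondrial for the retained cells.
#'
#' @param counts SingleCellExperiment or genes-by-cells matrix of called
#'   cells.
#' @param mito_max_pct maximum percent mitochondrial (strict).
#' @param mito_prefix prefix of mitochondrial gene names.
#' @return list(counts = filtered object, cell_table = QC data.frame of the
#'   retained cells).
#' @export
qcFilter <- function(counts, mito_max_pct = 5, mito_prefix = "MT-") {
    m <- .get_counts(counts)
    if (!any(startsWith(rownames(m), mito_prefix))) {
        warning("no gene matches the mitochondrial prefix '", mito_prefix,
                "'; skipping the mitochondrial filter")
        ct <- cellMetrics(counts, mito_prefix)
        ct$qc_pass <- TRUE
        return(list(counts = counts, cell_table = ct))
    }
    ct <- cellMetrics(counts, mito_prefix)
    keep <- ct$pct_mito <= mito_max_pct
    ct$qc_pass <- keep
    out <- if (is(counts, "SummarizedExperiment"))
        counts[, keep] else m[, keep, drop = FALSE]
    list(counts = out, cell_table = ct[keep, , drop = FALSE])
}

#' Remove spiked control-cell clusters
#'
#' Given an initial clustering, removes every cluster in which more than half
#' of the cells detect the control transgene feature — the automated
#' analogue of excluding a spiked-in control-cell cluster identified by its
#' selection-marker transgene.
#'
#' @param counts SingleCellExperiment or genes-by-cells matrix.
#' @param clusters cluster label per cell.
#' @param control_feature gene id of the transgene.
#' @param detect_fraction fraction of detecting cells above which a cluster
#'   is removed (default 0.5, strict).
#' @return list(counts = filtered object, removed_clusters = labels removed).
#' @export
removeControlCells <- function(counts, clusters, control_feature,
                               detect_fraction = 0.5) {
    m <- .get_counts(counts)
    if (!control_feature %in% rownames(m))
        stop("control feature '", control_feature,
             "' is absent from the gene axis")
    det <- as.numeric(m[control_feature, ] > 0)
    frac <- tapply(det, clusters, mean)
    bad <- names(frac)[frac > detect_fraction]
    keep <- !(as.character(clusters) %in% bad)
    out <- if (is(counts, "SummarizedExperiment"))
        counts[, keep] else m[, keep, drop = FALSE]
    list(counts = out, removed_clusters = bad)
}

#' Library-level QC for plate/microfluidic (C1-style) data
#'
#' Flags libraries failing robust outlier rules on depth and detected genes
#' (below median - 3 MAD on the log scale) or exceeding thresholds on
#' spike-in and mitochondrial fractions.
#'
#' @param metrics data.frame with columns \code{reads_in_features},
#'   \code{genes_detected}, \code{saturation}, \code{ercc_fraction},
#'   \code{mito_fraction}.
#' @param nmads MAD multiplier for the lower-tail rules.
#' @param max_ercc,max_mito upper thresholds on the fraction columns.
#' @return logical pass flag per library.
#' @export
qcFilterC1 <- function(metrics, nmads = 3, max_ercc = 0.2, max_mito = 0.2) {
    need <- c("reads_in_features", "genes_detected", "saturation",
              "ercc_fraction", "mito_fraction")
    miss <- setdiff(need, colnames(metrics))
    if (length(miss)) stop("missing metric columns: ",
                           paste(miss, collapse = ", "))
    low_tail <- function(x) {
        lx <- log10(x + 1)
        lx >= median(lx) - nmads * mad(lx)
    }
    pass <- low_tail(metrics$reads_in_features) &
        low_tail(metrics$genes_detected) &
        metrics$ercc_fraction <= max_ercc &
        metrics$mito_fraction <= max_mito &
        metrics$reads_in_features > 0
    setNames(pass, rownames(metrics))
}
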