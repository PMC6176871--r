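#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects \code{matrix.mtx} (optionally gzipped), \code{barcodes.tsv} and
#' \code{genes.tsv} or \code{features.tsv} (gene id, optional symbol) in one
#' directory. Orientation on disk is genes x cells with 1-based coordinates,
#' the 10x convention.
#'
#' @param dir_path directory containing the three files.
#' @return A \link[SingleCellExperiment]{SingleCellExperiment} with a sparse
#'   integer \code{counts} assay; \code{rowData} carries gene ids and
#'   symbols.
#' @export
readMtxTriplet <- function(dir_path) {
    pick <- function(names) {
        for (nm in names) {
            p <- file.path(dir_path, nm)
            if (file.exists(p)) return(p)
        }
        stop("missing file in ", dir_path, ": one of ",
             paste(names, collapse = ", "))
    }
    mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
    bcf <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
    gnf <- pick(c("genes.tsv", "features.tsv", "genes.tsv.gz",
                  "features.tsv.gz"))
    m <- tryCatch(Matrix::readMM(mtx),
                  error = function(e) stop("malformed matrix file ", mtx, ": ",
                                           conditionMessage(e)))
    barcodes <- readLines(bcf)
    genes <- read.delim(gnf, header = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(barcodes))
        stop("duplicate barcodes in ", bcf)
    if (anyDuplicated(genes[[1]]))
        stop("duplicate gene ids in ", gnf)
    if (nrow(m) != nrow(genes))
        stop("dimension mismatch: ", mtx, " has ", nrow(m), " rows but ",
             gnf, " lists ", nrow(genes), " genes")
    if (ncol(m) != length(barcodes))
        stop("dimension mismatch: ", mtx, " has ", ncol(m), " columns but ",
             bcf, " lists ", length(barcodes), " barcodes")
    if (any(m@x < 0) || any(m@x != round(m@x)))
        stop("matrix file ", mtx, " contains non-count entries")
    dimnames(m) <- list(genes[[1]], barcodes)
    sym <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
    SingleCellExperiment(
        assays = list(counts = methods::as(m, "CsparseMatrix")),
        rowData = DataFrame(gene_id = genes[[1]], gene_symbol = sym,
                            row.names = genes[[1]]),
        colData = DataFrame(barcode = barcodes, row.names = barcodes))
}

#' Write a 10x-style Matrix Market triplet directory
#'
#' Inverse of \code{\link{readMtxTriplet}}; round-trips bit-exactly.
#'
#' @param x SingleCellExperiment or genes-by-cells matrix with dimnames.
#' @param dir_path output directory (created if needed).
#' @return \code{dir_path}, invisibly.
#' @export
writeMtxTriplet <- function(x, dir_path) {
    m <- .get_counts(x)
    dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    file.path(dir_path, "matrix.mtx"))
    writeLines(colnames(m), file.path(dir_path, "barcodes.tsv"))
    sym <- if (is(x, "SummarizedExperiment") &&
               "gene_symbol" %in% colnames(SummarizedExperiment::rowData(x)))
        SummarizedExperiment::rowData(x)$gene_symbol else rownames(m)
    write.table(data.frame(rownames(m), sym),
                file.path(dir_path, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir_path)
}

#' Read a dense count table with spike-in partitioning
#'
#' Reads a TSV/CSV with gene rows and cell columns (C1-style), splitting off
#' rows whose name carries the spike-in prefix (ERCC controls by default).
#'
#' @param path file path; delimiter inferred from the extension
#'   (.csv = comma, otherwise tab).
#' @param spike_prefix prefix marking spike-in rows.
#' @return list(counts = SingleCellExperiment of the biological rows,
#'   spikes = SingleCellExperiment of the spike-in rows, possibly 0-row).
#' @export
readDenseTable <- function(path, spike_prefix = "ERCC-") {
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    tab <- read.delim(path, sep = sep, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m) || any(m != round(m)) || any(m < 0))
        stop("dense table contains non-integer or negative entries: ", path)
    storage.mode(m) <- "integer"
    spike <- startsWith(rownames(m), spike_prefix)
    make <- function(mm) SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(mm, sparse = TRUE)),
        colData = DataFrame(barcode = colnames(mm), row.names = colnames(mm)))
    list(counts = make(m[!spike, , drop = FALSE]),
         spikes = make(m[spike, , drop = FALSE]))
}

#' Merge count matrices from several samples
#'
#' Gene axes are reconciled by gene id (outer union; absent genes count 0).
#' No depth normalization or down-sampling is performed: every count value
#' is preserved. Barcodes are suffixed with the sample label to stay unique.
#'
#' @param samples list of SingleCellExperiments or genes-by-cells matrices.
#' @param batch_labels character vector, one label per sample.
#' @return A SingleCellExperiment whose colData records \code{batch} and
#'   \code{sample} per cell.
#' @export
mergeSamples <- function(samples, batch_labels) {
    stopifnot(length(samples) == length(batch_labels))
    mats <- lapply(samples, function(s)
        methods::as(Matrix::Matrix(.get_counts(s), sparse = TRUE),
                    "CsparseMatrix"))
    all_genes <- Reduce(union, lapply(mats, rownames))
    out <- vector("list", length(mats))
    for (i in seq_along(mats)) {
        m <- mats[[i]]
        full <- Matrix::Matrix(0, nrow = length(all_genes), ncol = ncol(m),
                               sparse = TRUE,
                               dimnames = list(all_genes, NULL))
        full[rownames(m), ] <- m
        colnames(full) <- paste0(colnames(m), "-", batch_labels[i])
        out[[i]] <- full
    }
    merged <- do.call(cbind, out)
    if (anyDuplicated(colnames(merged)))
        stop("duplicate barcodes after sample suffixing")
    batch <- rep(batch_labels, vapply(mats, ncol, integer(1)))
    SingleCellExperiment(
        assays = list(counts = merged),
        colData = DataFrame(barcode = colnames(merged), batch = batch,
                            sample = batch, row.names = colnames(merged)))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes per line).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Read / write an ortholog map TSV
#'
#' Schema: gene_A, gene_B, homology_class, pct_identity_AtoB,
#' pct_identity_BtoA. Validated on read.
#'
#' @param path TSV file.
#' @return data.frame (see \code{\link{validateOrthologMap}}).
#' @export
readOrthologMap <- function(path) {
    map <- read.delim(path, stringsAsFactors = FALSE)
    validateOrthologMap(map)
    map
}

#' @rdname readOrthologMap
#' @param map validated ortholog data.frame.
#' @export
writeOrthologMap <- function(map, path) {
    validateOrthologMap(map)
    write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a YAML pipeline configuration
#'
#' Unknown top-level keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @param allowed character vector of permitted top-level keys.
#' @return Named list.
#' @export
readPipelineConfig <- function(path,
                               allowed = c("paths", "stages", "qc",
                                           "normalization", "hvg", "network",
                                           "markers", "rf", "entropy",
                                           "diffusion", "seed")) {
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg
}
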