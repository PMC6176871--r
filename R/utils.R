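#' Area under the ROC curve by rank sum
#'
#' AUC of a numeric score for separating a positive group from the rest,
#' computed as the Mann-Whitney statistic with midranks, so tied scores count
#' one half. This is the primitive behind marker ranking and feature
#' specificity scores.
#'
#' @param x numeric scores, one per observation.
#' @param positive logical vector, TRUE for the positive group.
#' @return AUC in [0,1]; NA if either group is empty.
#' @export
aucRank <- function(x, positive) {
    n1 <- sum(positive)
    n2 <- sum(!positive)
    if (n1 == 0L || n2 == 0L) return(NA_real_)
    r <- rank(x, ties.method = "average")
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# dense numeric matrix from possibly-sparse input
.as_dense <- function(m) {
    if (is(m, "Matrix")) as.matrix(m) else m
}

# counts assay from an SCE or pass through a matrix
.get_counts <- function(x) {
    if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts")
    else x
}

# column totals that work for sparse and dense
.col_totals <- function(m) {
    if (is(m, "Matrix")) Matrix::colSums(m) else colSums(m)
}

# draw a derived integer seed for a named substream, keeping within 2^31
# (double arithmetic: the product can exceed integer range)
.substream_seed <- function(seed, tag) {
    as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(tag))) %% 2147483587)
}

# renumber integer labels by decreasing group size (1 = largest)
.relabel_by_size <- function(labels) {
    tab <- sort(table(labels), decreasing = TRUE)
    map <- setNames(seq_along(tab), names(tab))
    as.integer(map[as.character(labels)])
}

#' Write a structured per-stage log record
#'
#' Pipelines call this after each stage to record dimensions and decisions;
#' records accumulate in a manifest list.
#'
#' @param manifest list being accumulated.
#' @param stage stage name.
#' @param ... named fields to record.
#' @return The manifest with one record appended.
#' @export
logStage <- function(manifest, stage, ...) {
    rec <- list(stage = stage, ...)
    message("[", stage, "] ",
            paste(names(rec)[-1], unlist(rec[-1]), sep = "=", collapse = " "))
    manifest[[length(manifest) + 1L]] <- rec
    manifest
}
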