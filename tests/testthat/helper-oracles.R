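# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# AUC by exhaustive pair counting; ties count one half
auc_brute <- function(x, positive) {
    a <- x[positive]
    b <- x[!positive]
    mean(outer(a, b, function(u, v) (u > v) + 0.5 * (u == v)))
}

# upper-tail hypergeometric by direct summation
hyper_brute <- function(overlap, set_size, query_size, universe) {
    ks <- overlap:min(set_size, query_size)
    sum(choose(set_size, ks) * choose(universe - set_size, query_size - ks)) /
        choose(universe, query_size)
}

# adjusted Rand index (mclust is available in the test environment)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# counts matrix out of a simulation result
sim_counts <- function(sim) {
    as.matrix(SummarizedExperiment::assay(sim$counts, "counts"))
}

# library-size log-normalization shortcut for fixtures
libnorm <- function(m) {
    lib <- colSums(m)
    logNormalize(m, lib / mean(lib))
}

# per-barcode batch vector covering ambient barcodes too
full_batch <- function(sim) {
    bc <- colnames(SummarizedExperiment::assay(sim$counts))
    batch <- setNames(rep("batch1", length(bc)), bc)
    batch[names(sim$truth$batch_labels)] <- sim$truth$batch_labels
    batch
}

# small planted-module expression fixture: `nmod` correlated blocks of
# `gsz` genes plus `noise` independent genes
module_fixture <- function(nmod = 4, gsz = 60, ncell = 200, noise = 60,
                           r = 0.8, seed = 1) {
    set.seed(seed)
    lat <- matrix(rnorm(nmod * ncell), nmod)
    expr <- do.call(rbind, lapply(seq_len(nmod), function(k)
        t(vapply(seq_len(gsz),
                 function(g) sqrt(r) * lat[k, ] + sqrt(1 - r) * rnorm(ncell),
                 numeric(ncell)))))
    if (noise > 0)
        expr <- rbind(expr, matrix(rnorm(noise * ncell), noise, ncell))
    rownames(expr) <- sprintf("G%03d", seq_len(nrow(expr)))
    colnames(expr) <- sprintf("C%03d", seq_len(ncell))
    list(expr = expr, truth = c(rep(seq_len(nmod), each = gsz),
                                rep(0L, noise)))
}

# toy ortholog map with identities straddling the 75% filter and planted
# non-one2one rows
toy_ortholog_map <- function() {
    data.frame(
        gene_A = c(paste0("A", 1:6), "A7", "A7", "A8", "A9"),
        gene_B = c(paste0("B", 1:6), "B7", "B7b", "B8", "B8"),
        homology_class = c(rep("one2one", 6), "one2many", "one2many",
                           "many2many", "many2many"),
        pct_identity_AtoB = c(90, 80, 76, 74.9, 70, 95, 99, 99, 99, 99),
        pct_identity_BtoA = c(88, 82, 75, 80, 65, 60, 99, 99, 99, 99),
        stringsAsFactors = FALSE)
}
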