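#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame
NULL

# canonical 13 mitochondrial protein-coding genes; prefix is configurable
.MITO_GENES <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
                 "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB")

.TRANSGENE <- "TRANSGENE-BSD"

# NB draw with variance mu + phi*mu^2; phi = 0 degenerates to Poisson
.rnb <- function(n, mu, phi) {
    if (all(phi == 0)) return(rpois(n, mu))
    rnbinom(n, mu = mu, size = 1 / phi)
}

# lognormal relative-abundance profile for a gene panel
.base_profile <- function(n) rlnorm(n, meanlog = 0, sdlog = 1.2)

#' Simulate a droplet scRNA-seq experiment with ground truth
#'
#' Generates a genes-by-barcodes UMI count matrix whose per-barcode totals
#' form a two-component mixture: an ambient mode of empty gel beads drawn
#' from a scaled-down library-wide mean profile, and a cell mode with
#' negative-binomial counts, planted cluster structure (disjoint per-cluster
#' marker genes shifted up by the configured log2 fold change),
#' gene-by-batch multiplicative effects, 13 mitochondrial genes whose share
#' of each cell's library follows the configured mean fraction, and a
#' spiked-in control-cell cluster expressing a dedicated transgene feature.
#'
#' @param config a \linkS4class{SimConfig}; its seed fully determines the
#'   output.
#' @return A list with \code{counts} (a \link[SingleCellExperiment]{SingleCellExperiment}
#'   holding a sparse counts assay over all barcodes) and \code{truth}, a
#'   list with \code{is_cell}, \code{cell_labels} (levels \code{1..K} plus
#'   \code{"control"}), \code{batch_labels}, \code{marker_genes} (per-cluster
#'   gene lists with the true log2 fold change), \code{mito_fraction} and
#'   \code{totals_expected} per cell.
#' @examples
#' sim <- simulateDropletExperiment(simConfig(n_genes = 300,
#'     n_cells_per_cluster = c(60, 60), ambient_barcodes = 200, seed = 1))
#' @export
simulateDropletExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (config@ambient_barcodes > 0L &&
        config@ambient_mean_umi >= config@cell_mean_umi)
        stop("ambient_mean_umi must be below cell_mean_umi: ",
             "the two barcode modes would overlap")
    set.seed(config@seed)

    K <- length(config@n_cells_per_cluster)
    G <- config@n_genes
    gene_ids <- sprintf("GENE%05d", seq_len(G))
    mito_ids <- paste0(config@mito_prefix, .MITO_GENES)
    all_genes <- c(gene_ids, mito_ids, .TRANSGENE)
    Gt <- length(all_genes)

    base <- .base_profile(G)
    n_mark <- round(config@de_fraction * G)
    marker_idx <- if (n_mark > 0) sample(G, n_mark) else integer()
    marker_split <- if (n_mark > 0)
        split(marker_idx, rep(seq_len(K), length.out = n_mark)) else
        rep(list(integer()), K)

    # per-cluster relative profiles over regular genes
    cluster_w <- matrix(rep(base, K), nrow = G)
    for (k in seq_len(K))
        cluster_w[marker_split[[k]], k] <- cluster_w[marker_split[[k]], k] *
            2^config@logfc

    n_real <- sum(config@n_cells_per_cluster)
    n_ctrl <- round(config@control_cell_fraction * n_real)
    ctrl_w <- .base_profile(G)

    labels <- c(rep(as.character(seq_len(K)), config@n_cells_per_cluster),
                rep("control", n_ctrl))
    n_cells <- length(labels)
    batch <- sample(rep_len(seq_len(config@n_batches), n_cells))
    batch_fac <- matrix(2^rnorm(G * config@n_batches, 0, config@batch_logfc_sd),
                        nrow = G)

    # per-cell mitochondrial fraction around the configured mean
    mf <- config@mito_fraction_mean
    mito_frac <- if (mf > 0)
        stats::rbeta(n_cells, shape1 = mf * 40, shape2 = (1 - mf) * 40) else
        rep(0, n_cells)
    mito_w <- .base_profile(length(mito_ids))
    mito_w <- mito_w / sum(mito_w)

    totals <- rlnorm(n_cells, log(config@cell_mean_umi) - 0.25^2 / 2, 0.25)
    phi <- rep_len(config@nb_dispersion, Gt)

    counts <- matrix(0L, nrow = Gt, ncol = n_cells)
    for (i in seq_len(n_cells)) {
        w <- if (labels[i] == "control") ctrl_w else
            cluster_w[, as.integer(labels[i])]
        w <- w * batch_fac[, batch[i]]
        w <- w / sum(w)
        tg_share <- if (labels[i] == "control") 0.03 else 0
        mu <- c(w * (1 - mito_frac[i] - tg_share),
                mito_w * mito_frac[i],
                tg_share) * totals[i]
        counts[, i] <- .rnb(Gt, mu, phi)
    }

    # ambient barcodes: library-wide mean profile, scaled down
    n_amb <- config@ambient_barcodes
    if (n_amb > 0L) {
        amb_profile <- rowMeans(counts)
        amb_profile <- amb_profile / sum(amb_profile)
        amb_tot <- rlnorm(n_amb, log(config@ambient_mean_umi) - 0.3^2 / 2, 0.3)
        amb <- matrix(rpois(Gt * n_amb, amb_profile %o% amb_tot), nrow = Gt)
        counts <- cbind(counts, amb)
    }
    n_bc <- n_cells + n_amb
    ord <- sample(n_bc)
    counts <- counts[, ord, drop = FALSE]
    is_cell <- (seq_len(n_bc) <= n_cells)[ord]
    barcodes <- sprintf("BC%06d", seq_len(n_bc))
    dimnames(counts) <- list(all_genes, barcodes)

    sce <- SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = DataFrame(barcode = barcodes, row.names = barcodes))
    marker_genes <- lapply(marker_split, function(ix)
        data.frame(gene = gene_ids[ix], log2fc = config@logfc))
    names(marker_genes) <- as.character(seq_len(K))

    cell_bc <- barcodes[is_cell]
    cell_ord <- order(match(which(is_cell), seq_len(n_bc)))
    # map truth vectors (cell order before shuffling) onto shuffled barcodes
    orig_pos <- ord[is_cell]    # position in pre-shuffle layout
    truth <- list(
        is_cell = setNames(is_cell, barcodes),
        cell_labels = setNames(labels[orig_pos], cell_bc),
        batch_labels = setNames(paste0("batch", batch[orig_pos]), cell_bc),
        mito_fraction = setNames(mito_frac[orig_pos], cell_bc),
        totals_expected = setNames(totals[orig_pos], cell_bc),
        marker_genes = marker_genes,
        transgene = .TRANSGENE,
        mito_genes = mito_ids)
    list(counts = sce, truth = truth)
}

#' Simulate a two-species dataset pair linked by an ortholog map
#'
#' Both species share the same planted cluster structure. Markers of
#' conserved clusters are drawn from one-to-one ortholog pairs at high
#' sequence identity, so they translate across species; divergent clusters
#' receive species-private markers. The map additionally carries planted
#' one-to-many / many-to-one / many-to-many rows and one-to-one identities
#' spanning \code{identity_range}.
#'
#' @param config a \linkS4class{SimConfig} (ambient barcodes and control
#'   cells are not simulated here).
#' @param n_orthologs number of one-to-one ortholog pairs; must not exceed
#'   \code{n_genes}.
#' @param identity_range length-2 numeric, percent-identity range of
#'   non-marker one-to-one rows.
#' @param divergent_clusters integer ids of clusters whose markers are
#'   species-private.
#' @param n_multi planted rows per non-one2one homology class.
#' @return list(counts_A, counts_B, map, truth); counts are
#'   SingleCellExperiments, map is a validated ortholog data.frame, truth
#'   records per-species labels, marker sets and conserved/divergent flags.
#' @export
simulateTwoSpecies <- function(config, n_orthologs = round(config@n_genes * 0.8),
                               identity_range = c(60, 99),
                               divergent_clusters = integer(),
                               n_multi = 10L) {
    stopifnot(is(config, "SimConfig"))
    if (n_orthologs > config@n_genes)
        stop("n_orthologs exceeds the number of genes")
    K <- length(config@n_cells_per_cluster)
    if (length(divergent_clusters) &&
        !all(divergent_clusters %in% seq_len(K)))
        stop("divergent_clusters must be cluster ids")
    set.seed(config@seed)

    G <- config@n_genes
    genes_A <- sprintf("HA%05d", seq_len(G))
    genes_B <- sprintf("MB%05d", seq_len(G))
    ortho_idx <- seq_len(n_orthologs)   # gene i of A maps to gene i of B

    n_mark <- round(config@de_fraction * G)
    per_k <- max(1L, n_mark %/% K)
    # conserved markers live inside the ortholog set, private ones outside it
    pool_cons <- sample(ortho_idx)
    pool_priv_A <- sample(setdiff(seq_len(G), ortho_idx))
    pool_priv_B <- sample(setdiff(seq_len(G), ortho_idx))
    mark_A <- mark_B <- vector("list", K)
    ci <- 0L; pa <- 0L; pb <- 0L
    for (k in seq_len(K)) {
        if (k %in% divergent_clusters) {
            mark_A[[k]] <- pool_priv_A[pa + seq_len(per_k)]; pa <- pa + per_k
            mark_B[[k]] <- pool_priv_B[pb + seq_len(per_k)]; pb <- pb + per_k
        } else {
            ix <- pool_cons[ci + seq_len(per_k)]; ci <- ci + per_k
            mark_A[[k]] <- ix
            mark_B[[k]] <- ix
        }
    }
    # in species B a divergent cluster partially mimics the nearest conserved
    # cluster on the shared (orthologous) axis, so transferred labels confuse
    # the two - the planted analogue of cross-species misclassification
    mimic_of <- setNames(rep(NA_integer_, K), as.character(seq_len(K)))
    conserved_ids <- setdiff(seq_len(K), divergent_clusters)
    shift_B <- mark_B   # genes up-shifted in expression (may overlap)
    for (k in divergent_clusters) {
        if (!length(conserved_ids)) break
        tc <- conserved_ids[which.min(abs(conserved_ids - k))]
        mimic_of[as.character(k)] <- tc
        borrow <- mark_B[[tc]][seq_len(ceiling(length(mark_B[[tc]]) / 2))]
        shift_B[[k]] <- c(shift_B[[k]], borrow)
    }

    base <- .base_profile(G)
    sim_species <- function(marks, genes, seed) {
        set.seed(seed)
        W <- matrix(rep(base, K), nrow = G)
        for (k in seq_len(K)) W[marks[[k]], k] <- W[marks[[k]], k] * 2^config@logfc
        labels <- rep(seq_len(K), config@n_cells_per_cluster)
        n <- length(labels)
        totals <- rlnorm(n, log(config@cell_mean_umi) - 0.25^2 / 2, 0.25)
        phi <- rep_len(config@nb_dispersion, G)
        cnt <- matrix(0L, nrow = G, ncol = n)
        for (i in seq_len(n)) {
            w <- W[, labels[i]]
            cnt[, i] <- .rnb(G, w / sum(w) * totals[i], phi)
        }
        bc <- sprintf("C%05d", seq_len(n))
        dimnames(cnt) <- list(genes, bc)
        sce <- SingleCellExperiment(
            assays = list(counts = Matrix::Matrix(cnt, sparse = TRUE)),
            colData = DataFrame(barcode = bc, cluster = factor(labels),
                                row.names = bc))
        sce
    }
    sce_A <- sim_species(mark_A, genes_A, .substream_seed(config@seed, "spA"))
    sce_B <- sim_species(shift_B, genes_B, .substream_seed(config@seed, "spB"))

    set.seed(.substream_seed(config@seed, "map"))
    marker_one2one <- sort(unique(unlist(mark_A[setdiff(seq_len(K),
                                                        divergent_clusters)])))
    idn <- runif(n_orthologs, identity_range[1], identity_range[2])
    # conserved markers must survive the >= 75% identity filter
    idn[marker_one2one] <- runif(length(marker_one2one), 85, 99)
    map <- data.frame(
        gene_A = genes_A[ortho_idx],
        gene_B = genes_B[ortho_idx],
        homology_class = "one2one",
        pct_identity_AtoB = idn,
        pct_identity_BtoA = pmin(100, idn + rnorm(n_orthologs, 0, 1)),
        stringsAsFactors = FALSE)
    if (n_multi > 0L) {
        extra <- function(class, tag) {
            data.frame(
                gene_A = sprintf("HA%05d", G + seq_len(n_multi) +
                                     n_multi * tag),
                gene_B = sprintf("MB%05d", G + seq_len(n_multi) +
                                     n_multi * tag),
                homology_class = class,
                pct_identity_AtoB = runif(n_multi, 40, 99),
                pct_identity_BtoA = runif(n_multi, 40, 99),
                stringsAsFactors = FALSE)
        }
        map <- rbind(map, extra("one2many", 0L), extra("many2one", 1L),
                     extra("many2many", 2L))
    }
    validateOrthologMap(map)

    truth <- list(
        cell_labels_A = SummarizedExperiment::colData(sce_A)$cluster,
        cell_labels_B = SummarizedExperiment::colData(sce_B)$cluster,
        marker_genes_A = lapply(mark_A, function(ix) genes_A[ix]),
        marker_genes_B = lapply(mark_B, function(ix) genes_B[ix]),
        conserved = setNames(!(seq_len(K) %in% divergent_clusters),
                             as.character(seq_len(K))),
        mimic_of = mimic_of)
    list(counts_A = sce_A, counts_B = sce_B, map = map, truth = truth)
}

#' Simulate a one-dimensional (optionally branched) expression trajectory
#'
#' Cells receive a latent time t in [0,1]; a planted fraction of genes vary
#' smoothly along t through linear or sigmoid programs (two thirds rising
#' toward 2^logfc, one third falling), the remainder are static. With
#' \code{branch = TRUE} a single branch point at t = 0.5 splits cells into
#' two lineages with lineage-specific late programs.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param branch logical; add a branch point at t = 0.5.
#' @return list(counts, truth) with truth fields \code{true_pseudotime},
#'   \code{branch_labels} (single lineage when \code{branch = FALSE}) and
#'   \code{dynamic_genes}.
#' @export
simulateTrajectory <- function(config, branch = FALSE) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    G <- config@n_genes
    n <- sum(config@n_cells_per_cluster)
    genes <- sprintf("GENE%05d", seq_len(G))
    tt <- sort(runif(n))
    branch_lab <- rep(1L, n)
    if (branch)
        branch_lab[tt > 0.5] <- sample(c(1L, 2L), sum(tt > 0.5), replace = TRUE)

    n_dyn <- max(2L, round(config@de_fraction * G))
    dyn <- sample(G, n_dyn)
    up <- dyn[seq_len(ceiling(2 * n_dyn / 3))]
    down <- setdiff(dyn, up)
    shape <- sample(c("linear", "sigmoid"), n_dyn, replace = TRUE)
    names(shape) <- as.character(dyn)
    mid <- runif(n_dyn, 0.3, 0.7); names(mid) <- as.character(dyn)
    # late branch-2-specific program
    br2 <- if (branch) sample(up, max(1L, length(up) %/% 4)) else integer()

    prog <- function(g, t, b) {
        s <- if (shape[as.character(g)] == "linear") t else
            1 / (1 + exp(-12 * (t - mid[as.character(g)])))
        if (g %in% br2 && b == 1L) s <- s * (t <= 0.5) # only branch 2 keeps it
        if (g %in% down) 1 - s else s
    }

    base <- .base_profile(G)
    # dynamic genes share a common moderate baseline so their summed signal
    # tracks latent time instead of being dominated by a few abundant genes
    base[dyn] <- 3
    phi <- rep_len(config@nb_dispersion, G)
    totals <- rlnorm(n, log(config@cell_mean_umi) - 0.25^2 / 2, 0.25)
    cnt <- matrix(0L, nrow = G, ncol = n)
    mult <- matrix(1, nrow = G, ncol = n)
    for (g in dyn)
        mult[g, ] <- 2^(config@logfc *
                        vapply(seq_len(n),
                               function(i) prog(g, tt[i], branch_lab[i]),
                               numeric(1)))
    # scaled to the baseline library size: dynamic genes add signal on top,
    # so the summed dynamic-gene signal tracks latent time
    for (i in seq_len(n))
        cnt[, i] <- .rnb(G, base * mult[, i] * totals[i] / sum(base), phi)
    bc <- sprintf("C%05d", seq_len(n))
    dimnames(cnt) <- list(genes, bc)
    sce <- SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(cnt, sparse = TRUE)),
        colData = DataFrame(barcode = bc, row.names = bc))
    truth <- list(true_pseudotime = setNames(tt, bc),
                  branch_labels = setNames(branch_lab, bc),
                  dynamic_genes = genes[dyn],
                  up_genes = genes[up], down_genes = genes[down])
    list(counts = sce, truth = truth)
}

#' Simulate cell-cycle gene-pair structure
#'
#' For each phase (G1, S, G2M), \code{n_pairs_per_phase} ordered gene pairs
#' (g_hi, g_lo) are planted such that expression of g_hi exceeds g_lo in at
#' least 90\% of that phase's cells and at most 10\% of the others, by a
#' 16-fold mean separation that is reversed outside the phase. Cells carry
#' cluster labels from the configuration; the last cluster is proliferative
#' (G2M-enriched), supporting G2M-proportion-by-cluster summaries.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param n_pairs_per_phase pairs planted per phase (>= 1).
#' @return list(counts, truth, pairs); pairs is a named list (G1, S, G2M)
#'   of two-column character matrices (hi, lo); truth records phase labels,
#'   cluster labels and the proliferative cluster id.
#' @export
simulateCellCycle <- function(config, n_pairs_per_phase = 10L) {
    stopifnot(is(config, "SimConfig"), n_pairs_per_phase >= 1L)
    set.seed(config@seed)
    phases <- c("G1", "S", "G2M")
    K <- length(config@n_cells_per_cluster)
    labels <- rep(seq_len(K), config@n_cells_per_cluster)
    n <- length(labels)
    # last cluster is proliferative
    p_g2m <- ifelse(labels == K, 0.6, 0.1)
    phase <- character(n)
    for (i in seq_len(n)) {
        if (runif(1) < p_g2m[i]) phase[i] <- "G2M"
        else phase[i] <- sample(c("G1", "S"), 1L, prob = c(0.7, 0.3))
    }

    G <- config@n_genes
    n_pair_genes <- 2L * n_pairs_per_phase * length(phases)
    if (G < n_pair_genes + 10L) stop("n_genes too small for requested pairs")
    genes <- sprintf("GENE%05d", seq_len(G))
    base <- .base_profile(G)
    pair_gene_idx <- sample(G, n_pair_genes)
    base[pair_gene_idx] <- 5   # moderate, equal baseline for pair genes

    pairs <- list()
    W <- matrix(rep(base, n), nrow = G)
    idx <- pair_gene_idx
    for (p in phases) {
        hi <- idx[seq_len(n_pairs_per_phase)]
        lo <- idx[n_pairs_per_phase + seq_len(n_pairs_per_phase)]
        idx <- idx[-seq_len(2L * n_pairs_per_phase)]
        inphase <- phase == p
        W[hi, inphase] <- W[hi, inphase] * 2^2
        W[lo, inphase] <- W[lo, inphase] * 2^-2
        W[hi, !inphase] <- W[hi, !inphase] * 2^-2
        W[lo, !inphase] <- W[lo, !inphase] * 2^2
        pairs[[p]] <- cbind(hi = genes[hi], lo = genes[lo])
    }
    # mild cluster markers so clusters are separable
    n_mark <- max(K, round(config@de_fraction * G / 2))
    free <- setdiff(seq_len(G), pair_gene_idx)
    mk <- split(sample(free, n_mark), rep_len(seq_len(K), n_mark))
    for (k in seq_len(K)) {
        sel <- labels == k
        W[mk[[k]], sel] <- W[mk[[k]], sel] * 2^config@logfc
    }

    phi <- rep_len(config@nb_dispersion, G)
    totals <- rlnorm(n, log(config@cell_mean_umi) - 0.25^2 / 2, 0.25)
    cnt <- matrix(0L, nrow = G, ncol = n)
    for (i in seq_len(n))
        cnt[, i] <- .rnb(G, W[, i] / sum(W[, i]) * totals[i], phi)
    bc <- sprintf("C%05d", seq_len(n))
    dimnames(cnt) <- list(genes, bc)
    sce <- SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(cnt, sparse = TRUE)),
        colData = DataFrame(barcode = bc, cluster = factor(labels),
                            row.names = bc))
    truth <- list(phase_labels = setNames(phase, bc),
                  cell_labels = setNames(labels, bc),
                  proliferative_cluster = K,
                  marker_genes = lapply(mk, function(ix) genes[ix]))
    list(counts = sce, truth = truth, pairs = pairs)
}
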