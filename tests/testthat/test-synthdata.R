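test_that("simConfig validates its invariants", {
    expect_error(simConfig(de_fraction = 1.5), "fractions")
    expect_error(simConfig(nb_dispersion = -1), "dispersion")
    expect_s4_class(simConfig(), "SimConfig")
})

test_that("droplet simulation is deterministic and mode means are honored", {
    cfg <- simConfig(n_genes = 300, n_cells_per_cluster = c(60, 60),
                     ambient_barcodes = 300, seed = 8)
    s1 <- simulateDropletExperiment(cfg)
    s2 <- simulateDropletExperiment(cfg)
    expect_identical(sim_counts(s1), sim_counts(s2))
    expect_identical(s1$truth$cell_labels, s2$truth$cell_labels)

    # planted component totals within 10% of the configured mode means
    cfg2 <- simConfig(cell_mean_umi = 5000, ambient_mean_umi = 100,
                      n_cells_per_cluster = rep(200, 5),
                      ambient_barcodes = 4000, seed = 3)
    sim <- simulateDropletExperiment(cfg2)
    tot <- colSums(sim_counts(sim))
    is_cell <- sim$truth$is_cell
    expect_lt(abs(mean(tot[is_cell]) - 5000) / 5000, 0.1)
    expect_lt(abs(mean(tot[!is_cell]) - 100) / 100, 0.1)
    # cell totals dominate ambient totals in distribution
    expect_lt(median(tot[!is_cell]), median(tot[is_cell]))

    # counts are non-negative integers
    m <- sim_counts(sim)
    expect_true(all(m >= 0) && all(m == round(m)))
})

test_that("degenerate droplet configs behave as contracted", {
    cfg <- simConfig(n_genes = 200, n_cells_per_cluster = c(40, 40),
                     ambient_barcodes = 0, seed = 1)
    sim <- simulateDropletExperiment(cfg)
    expect_true(all(sim$truth$is_cell))
    expect_error(
        simulateDropletExperiment(simConfig(ambient_mean_umi = 6000,
                                            cell_mean_umi = 5000, seed = 1)),
        "below cell_mean_umi")
})

test_that("planted markers carry the configured fold change", {
    cfg <- simConfig(n_genes = 500, n_cells_per_cluster = rep(200, 3),
                     ambient_barcodes = 0, control_cell_fraction = 0,
                     n_batches = 1, logfc = 2, seed = 6)
    sim <- simulateDropletExperiment(cfg)
    m <- sim_counts(sim)
    cpm <- sweep(m, 2, colSums(m), "/") * 1e4
    labs <- sim$truth$cell_labels[colnames(m)]
    for (k in names(sim$truth$marker_genes)) {
        g <- sim$truth$marker_genes[[k]]$gene
        ratio <- log2(rowMeans(cpm[g, labs == k, drop = FALSE]) + 0.1) -
            log2(rowMeans(cpm[g, labs != k, drop = FALSE]) + 0.1)
        expect_lt(abs(median(ratio) - 2), 0.5)
        # marker sets disjoint across clusters
        others <- unlist(lapply(sim$truth$marker_genes[
            setdiff(names(sim$truth$marker_genes), k)], `[[`, "gene"))
        expect_length(intersect(g, others), 0)
    }
})

test_that("two-species simulation plants conserved and divergent structure", {
    cfg <- simConfig(n_genes = 400, de_fraction = 0.2,
                     n_cells_per_cluster = rep(80, 3), ambient_barcodes = 0,
                     control_cell_fraction = 0, n_batches = 1, seed = 4)
    expect_error(simulateTwoSpecies(cfg, n_orthologs = 1000), "exceeds")

    ts <- simulateTwoSpecies(cfg, n_orthologs = 300, n_multi = 20,
                             divergent_clusters = integer())
    # all markers map one-to-one when nothing is divergent
    one2one <- ts$map[ts$map$homology_class == "one2one", ]
    for (g in unlist(ts$truth$marker_genes_A))
        expect_true(g %in% one2one$gene_A)
    expect_equal(sum(ts$map$homology_class == "many2many"), 20)

    # ortholog-translated species-A markers separate species-B clusters
    eb <- libnorm(sim_counts(list(counts = ts$counts_B)))
    tr <- setNames(one2one$gene_B, one2one$gene_A)
    labs <- ts$truth$cell_labels_B
    aucs <- unlist(lapply(seq_along(ts$truth$marker_genes_A), function(k) {
        gB <- unname(tr[ts$truth$marker_genes_A[[k]]])
        vapply(gB, function(g) aucRank(eb[g, ], labs == k), numeric(1))
    }))
    expect_gt(mean(aucs), 0.9)
})

test_that("trajectory simulation orders expression along latent time", {
    # reference trajectory conditions: 800 genes, 500 cells
    cfg <- simConfig(n_genes = 800, n_cells_per_cluster = c(500), seed = 2)
    tra <- simulateTrajectory(cfg)
    m <- sim_counts(tra)
    dg <- tra$truth$dynamic_genes
    sig <- colSums(m[dg, ]) / colSums(m)
    expect_gte(cor(sig, tra$truth$true_pseudotime, method = "spearman"), 0.8)
    expect_true(all(tra$truth$branch_labels == 1L))

    trb <- simulateTrajectory(simConfig(n_genes = 400,
                                        n_cells_per_cluster = c(300),
                                        seed = 2), branch = TRUE)
    expect_setequal(unique(trb$truth$branch_labels), c(1L, 2L))
})

test_that("cell-cycle pairs satisfy the planted consistency contract", {
    cyc <- simulateCellCycle(simConfig(n_genes = 400,
                                       n_cells_per_cluster = rep(80, 3),
                                       seed = 5), n_pairs_per_phase = 5)
    expect_equal(sum(vapply(cyc$pairs, nrow, integer(1))), 3 * 5)
    m <- sim_counts(cyc)
    phase <- cyc$truth$phase_labels
    for (p in names(cyc$pairs)) {
        for (i in seq_len(nrow(cyc$pairs[[p]]))) {
            hi <- m[cyc$pairs[[p]][i, "hi"], ]
            lo <- m[cyc$pairs[[p]][i, "lo"], ]
            expect_gte(mean((hi > lo)[phase == p]), 0.9)
            expect_lte(mean((hi > lo)[phase != p]), 0.1)
        }
    }
})
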