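# shared end-to-end droplet fixture: default study conditions, one seed
droplet_fixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            sim <- simulateDropletExperiment(simConfig(seed = 2))
            res <- suppressWarnings(runDropletPipeline(
                sim$counts, batch = full_batch(sim),
                control_feature = sim$truth$transgene,
                tsne_runs = 2, jackstraw_reps = 25, seed = 4))
            cache <<- list(sim = sim, res = res)
        }
        cache
    }
})

test_that("droplet pipeline recovers planted clusters end-to-end", {
    fx <- droplet_fixture()
    truth <- fx$sim$truth$cell_labels[names(fx$res$clusters)]
    expect_gte(ari(fx$res$clusters, truth), 0.85)
    # control cells are gone, ambient barcodes were never called
    expect_false(any(truth == "control"))
    expect_true(all(fx$sim$truth$is_cell[colnames(fx$res$sce)]))
    # manifest records every stage
    stages <- vapply(fx$res$manifest, `[[`, character(1), "stage")
    expect_true(all(c("call_cells", "qc_filter", "remove_control_cells",
                      "pca_jackstraw", "graph_cluster", "markers") %in%
                    stages))
})

test_that("droplet pipeline stages can be toggled off", {
    sim <- simulateDropletExperiment(
        simConfig(n_genes = 300, n_cells_per_cluster = c(60, 60),
                  ambient_barcodes = 200, control_cell_fraction = 0,
                  n_batches = 1, seed = 6))
    res <- suppressWarnings(runDropletPipeline(
        sim$counts, tsne_runs = 1, jackstraw_reps = 25,
        stages = list(tsne = FALSE, markers = FALSE), seed = 1))
    stages <- vapply(res$manifest, `[[`, character(1), "stage")
    skipped <- vapply(res$manifest, function(r) isTRUE(r$skipped), logical(1))
    expect_true(skipped[stages == "tsne"])
    expect_null(res$tsne)
    expect_null(res$markers)
})

test_that("C1 pipeline selects the planted rank above its permuted control", {
    cfg <- simConfig(n_genes = 600, de_fraction = 0.25,
                     n_cells_per_cluster = rep(75, 4), ambient_barcodes = 0,
                     control_cell_fraction = 0, n_batches = 1,
                     cell_mean_umi = 20000, seed = 31)
    sim <- simulateDropletExperiment(cfg)
    res <- suppressMessages(suppressWarnings(
        runC1Pipeline(sim_counts(sim), rank_range = 2:6, n_runs = 15,
                      nmf_max_iter = 200, seed = 3)))
    expect_equal(chosenRank(res$consensus), 4L)
    truth <- sim$truth$cell_labels[names(consensusLabels(res$consensus))]
    expect_gte(ari(consensusLabels(res$consensus), truth), 0.85)
    met <- rankMetrics(res$consensus)
    ctl <- res$consensus@control_metrics
    expect_gt(met$cophenetic[met$rank == 4], ctl$cophenetic[ctl$rank == 4])
    # markers rank cluster-exclusive genes at the top
    expect_true(all(res$markers$auc >= 0 & res$markers$auc <= 1))
})

test_that("cross-species pipeline transfers conserved classes", {
    cfg <- simConfig(n_genes = 600, de_fraction = 0.2,
                     n_cells_per_cluster = rep(100, 4), ambient_barcodes = 0,
                     control_cell_fraction = 0, n_batches = 1,
                     cell_mean_umi = 5000, seed = 41)
    ts <- simulateTwoSpecies(cfg, n_orthologs = 450, divergent_clusters = 1L)
    ea <- libnorm(as.matrix(SummarizedExperiment::assay(ts$counts_A)))
    eb <- libnorm(as.matrix(SummarizedExperiment::assay(ts$counts_B)))
    res <- suppressMessages(runCrossSpecies(
        ea, ts$truth$cell_labels_A, eb, ts$truth$cell_labels_B, ts$map,
        run_rfe = FALSE, ntree = 300, seed = 3))
    conserved <- names(which(ts$truth$conserved))
    expect_gte(mean(res$recall[conserved]), 0.8)
    expect_equal(names(which.min(res$recall)), "1")
    # confusion rows are normalized
    expect_equal(unname(rowSums(res$transfer$confusion)),
                 rep(1, 4), tolerance = 1e-12)
    # specificity correlation is high for conserved clusters
    expect_gt(min(res$specificity_correlation[conserved]), 0.8)
})

test_that("pipelines are reproducible from (config, seed)", {
    sim <- simulateDropletExperiment(
        simConfig(n_genes = 300, n_cells_per_cluster = c(60, 60),
                  ambient_barcodes = 200, control_cell_fraction = 0,
                  n_batches = 1, seed = 8))
    r1 <- suppressWarnings(runDropletPipeline(
        sim$counts, tsne_runs = 1, jackstraw_reps = 25,
        stages = list(tsne = FALSE), seed = 9))
    r2 <- suppressWarnings(runDropletPipeline(
        sim$counts, tsne_runs = 1, jackstraw_reps = 25,
        stages = list(tsne = FALSE), seed = 9))
    expect_identical(r1$clusters, r2$clusters)
    expect_identical(r1$markers, r2$markers)
})
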