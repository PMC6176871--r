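test_that("diffusion map orders points on a line and flags duplicates", {
    # points exactly on a line: the first component must be strictly monotone
    x <- cbind(seq(0, 10, length.out = 80), 0)
    rownames(x) <- paste0("c", 1:80)
    dm <- diffusionMap(x, k_nn = 15, n_components = 3, cells_in_rows = TRUE)
    rho <- cor(diffusionComponents(dm)[, 1], x[, 1], method = "spearman")
    expect_equal(abs(rho), 1)
    # eigenvalues in (0, 1] and decreasing
    ev <- diffusionEigenvalues(dm)
    expect_true(all(ev > 0 & ev <= 1))
    expect_true(all(diff(ev) <= 1e-12))

    # duplicated cell gets identical coordinates
    xd <- rbind(x, dup = x[1, ])
    dmd <- diffusionMap(xd, k_nn = 15, n_components = 2,
                        cells_in_rows = TRUE)
    expect_equal(diffusionComponents(dmd)["dup", ],
                 diffusionComponents(dmd)["c1", ], tolerance = 1e-8)
})

test_that("diffusion pseudotime tracks planted linear and branched time", {
    cfg <- simConfig(n_genes = 600, n_cells_per_cluster = c(400), seed = 24)
    tra <- simulateTrajectory(cfg)
    expr <- libnorm(sim_counts(tra))
    dg <- tra$truth$dynamic_genes
    dm <- suppressWarnings(diffusionMap(expr[dg, ], k_nn = 500))
    root <- names(which.min(tra$truth$true_pseudotime))
    dm <- diffusionPseudotime(dm, root)
    expect_equal(unname(pseudotime(dm)[root]), 0)
    expect_gte(cor(pseudotime(dm), tra$truth$true_pseudotime,
                   method = "spearman"), 0.9)

    # pseudotime is invariant to cell order
    perm <- sample(ncol(expr))
    dm2 <- suppressWarnings(diffusionMap(expr[dg, perm], k_nn = 500))
    dm2 <- diffusionPseudotime(dm2, root)
    expect_equal(pseudotime(dm2)[names(pseudotime(dm))], pseudotime(dm),
                 tolerance = 1e-6)

    # branched: both tips lie beyond the branch point
    trb <- simulateTrajectory(simConfig(n_genes = 600,
                                        n_cells_per_cluster = c(400),
                                        seed = 25), branch = TRUE)
    eb <- libnorm(sim_counts(trb))
    dmb <- suppressWarnings(diffusionMap(eb[trb$truth$dynamic_genes, ],
                                         k_nn = 500))
    dmb <- diffusionPseudotime(dmb,
                               names(which.min(trb$truth$true_pseudotime)))
    pt <- pseudotime(dmb)
    tt <- trb$truth$true_pseudotime
    bl <- trb$truth$branch_labels
    bp_med <- median(pt[abs(tt - 0.5) < 0.05])
    expect_gt(median(pt[tt > 0.9 & bl == 1]), bp_med)
    expect_gt(median(pt[tt > 0.9 & bl == 2]), bp_med)
})

test_that("cycle pair training recovers planted pairs and respects limits", {
    cyc <- simulateCellCycle(simConfig(n_genes = 400,
                                       n_cells_per_cluster = rep(80, 3),
                                       seed = 26), n_pairs_per_phase = 5)
    tp <- trainCyclePairs(cyc$counts, cyc$truth$phase_labels,
                          consistency = 0.7)
    for (p in c("G1", "S", "G2M")) {
        planted <- paste(cyc$pairs[[p]][, 1], cyc$pairs[[p]][, 2])
        found <- paste(tp[[p]][, 1], tp[[p]][, 2])
        expect_true(all(planted %in% found))
        expect_false(anyDuplicated(found) > 0)
    }
    expect_error(trainCyclePairs(cyc$counts,
                                 rep("G1", ncol(cyc$counts))), "2 phases")
})

test_that("cycle scoring calls phases by pair majorities", {
    pairs <- list(G1 = cbind(hi = c("A1", "A2"), lo = c("B1", "B2")),
                  G2M = cbind(hi = c("C1", "C2"), lo = c("D1", "D2")))
    # cell 1: all G2M pairs satisfied, no G1; cell 2: half of each; cell 3 ties
    m <- rbind(A1 = c(0, 5, 1), A2 = c(0, 0, 1),
               B1 = c(5, 0, 1), B2 = c(5, 5, 1),
               C1 = c(5, 5, 1), C2 = c(5, 0, 1),
               D1 = c(0, 0, 1), D2 = c(0, 5, 1))
    colnames(m) <- c("c1", "c2", "c3")
    sc <- scoreCycle(m, pairs)
    expect_equal(sc["c1", "g1_score"], 0)
    expect_equal(sc["c1", "g2m_score"], 1)
    expect_equal(sc["c1", "phase"], "G2M")
    expect_equal(sc["c2", "phase"], "S")
    expect_true(is.na(sc["c3", "g1_score"]))
    expect_equal(sc["c3", "phase"], "S")
})

test_that("simulated cycle data are phased accurately with a G2M-top cluster", {
    cyc <- simulateCellCycle(simConfig(n_genes = 500,
                                       n_cells_per_cluster = rep(100, 3),
                                       seed = 27))
    sc <- scoreCycle(cyc$counts, cyc$pairs)
    expect_gte(mean(sc$phase == cyc$truth$phase_labels), 0.9)
    g2m <- g2mProportionByCluster(sc$phase, cyc$truth$cell_labels)
    expect_equal(names(g2m)[1],
                 as.character(cyc$truth$proliferative_cluster))
})
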