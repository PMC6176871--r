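#' Run the droplet (10x-style) analysis track
#'
#' Stage order: cell calling from the UMI density, mitochondrial QC, an
#' initial graph clustering to locate and remove the spiked control-cell
#' cluster, deconvolution size factors, log normalization, variable-gene
#' selection, cell-cycle scoring (when pairs are supplied), regression of
#' total UMIs, batch and cycle scores, PCA with jackstraw component
#' selection, final graph clustering, best-of-n t-SNE and AUC markers.
#' Individual stages can be toggled off; every stage is logged with its
#' input/output dimensions in the returned manifest.
#'
#' @param counts SingleCellExperiment or genes-by-barcodes count matrix over
#'   all barcodes.
#' @param batch optional batch label per barcode (same order as columns).
#' @param control_feature transgene gene id for control-cell removal (NULL
#'   skips the stage).
#' @param cycle_pairs cell-cycle gene pairs (NULL skips cycle scoring).
#' @param mito_prefix mitochondrial gene prefix.
#' @param min_umi_floor,mito_max_pct QC thresholds (250 and 5).
#' @param n_pc components assessed by the jackstraw.
#' @param k_neighbors,resolution graph clustering parameters.
#' @param tsne_runs,perplexity t-SNE parameters.
#' @param jackstraw_reps jackstraw permutation replicates.
#' @param stages named logical list overriding stage toggles
#'   (call_cells, qc, control_removal, cycle, regress, tsne, markers).
#' @param seed integer seed for every stochastic stage.
#' @return list with the filtered dataset (\code{sce}), \code{cell_table},
#'   \code{clusters}, \code{significant_pcs}, embeddings (\code{pca},
#'   \code{tsne}), \code{markers} and the stage \code{manifest}.
#' @export
runDropletPipeline <- function(counts, batch = NULL, control_feature = NULL,
                               cycle_pairs = NULL, mito_prefix = "MT-",
                               min_umi_floor = 250, mito_max_pct = 5,
                               n_pc = 10, k_neighbors = 20, resolution = 0.8,
                               tsne_runs = 10, perplexity = 30,
                               jackstraw_reps = 50,
                               stages = list(), seed = 1L) {
    on <- function(s) !identical(stages[[s]], FALSE)
    manifest <- list()
    m <- .get_counts(counts)
    if (is.null(batch)) batch <- rep("batch1", ncol(m))
    names(batch) <- colnames(m)

    if (on("call_cells")) {
        cc <- callCells(m, min_umi_floor = min_umi_floor)
        m <- m[, cc$is_cell, drop = FALSE]
        manifest <- logStage(manifest, "call_cells",
                             threshold = round(cc$threshold, 1),
                             cells = ncol(m))
        if (ncol(m) == 0L) stop("stage call_cells: no cells called")
    } else manifest <- logStage(manifest, "call_cells", skipped = TRUE)

    if (on("qc")) {
        qf <- qcFilter(m, mito_max_pct = mito_max_pct,
                       mito_prefix = mito_prefix)
        m <- .get_counts(qf$counts)
        cell_table <- qf$cell_table
        manifest <- logStage(manifest, "qc_filter", cells = ncol(m))
    } else {
        cell_table <- cellMetrics(m, mito_prefix)
        manifest <- logStage(manifest, "qc_filter", skipped = TRUE)
    }
    batch <- batch[colnames(m)]

    # quick normalization for the initial clustering pass
    quick_norm <- function(mm) {
        lib <- .col_totals(mm)
        logNormalize(mm, lib / mean(lib))
    }
    if (on("control_removal") && !is.null(control_feature)) {
        e0 <- quick_norm(m)
        hv0 <- selectVariableGenes(e0)
        if (length(hv0) < 10) hv0 <- rownames(e0)
        p0 <- pcaEmbed(e0, n_components = min(10, length(hv0) - 1,
                                              ncol(e0) - 1),
                       variable_genes = hv0)
        cl0 <- graphCluster(p0, k_neighbors = min(k_neighbors, ncol(m) - 1),
                            resolution = resolution, seed = seed)
        rc <- removeControlCells(m, cl0, control_feature)
        m <- .get_counts(rc$counts)
        batch <- batch[colnames(m)]
        cell_table <- cell_table[colnames(m), , drop = FALSE]
        manifest <- logStage(manifest, "remove_control_cells",
                             removed_clusters =
                                 paste(rc$removed_clusters, collapse = ","),
                             cells = ncol(m))
    } else manifest <- logStage(manifest, "remove_control_cells",
                                skipped = TRUE)

    sf <- pooledSizeFactors(m)
    expr <- logNormalize(m, sf)
    manifest <- logStage(manifest, "normalize", genes = nrow(expr),
                         cells = ncol(expr))
    # mitochondrial genes are excluded from the variable set: their shared
    # per-cell fraction is a QC covariate, not a cell-identity axis
    hvg <- setdiff(selectVariableGenes(expr),
                   rownames(expr)[startsWith(rownames(expr), mito_prefix)])
    if (length(hvg) < 10) hvg <- rownames(expr)
    manifest <- logStage(manifest, "variable_genes", n = length(hvg))

    if (on("cycle") && !is.null(cycle_pairs)) {
        cyc <- scoreCycle(m, cycle_pairs)
        cell_table$g1_score <- cyc$g1_score
        cell_table$g2m_score <- cyc$g2m_score
        cell_table$phase <- cyc$phase
        manifest <- logStage(manifest, "score_cycle",
                             g2m = sum(cyc$phase == "G2M"))
    } else manifest <- logStage(manifest, "score_cycle", skipped = TRUE)

    if (on("regress")) {
        cov <- data.frame(total_umis = log10(.col_totals(m) + 1))
        if (length(unique(batch)) > 1) cov$batch <- factor(batch)
        if (!is.null(cell_table$g1_score)) {
            cov$g1_score <- cell_table$g1_score
            cov$g2m_score <- cell_table$g2m_score
        }
        cov[is.na(cov)] <- 0
        expr_adj <- regressOut(expr[hvg, , drop = FALSE], cov)
        manifest <- logStage(manifest, "regress_out",
                             covariates = paste(colnames(cov),
                                                collapse = ","))
    } else {
        expr_adj <- expr[hvg, , drop = FALSE]
        manifest <- logStage(manifest, "regress_out", skipped = TRUE)
    }

    n_pc_use <- min(n_pc, nrow(expr_adj) - 1L, ncol(expr_adj) - 1L)
    pca <- pcaEmbed(expr_adj, n_components = n_pc_use)
    sig <- jackstrawPcs(expr_adj, n_pc = n_pc_use, n_reps = jackstraw_reps,
                        seed = .substream_seed(seed, "jack"))
    if (!length(sig)) sig <- seq_len(min(2L, n_pc_use))
    manifest <- logStage(manifest, "pca_jackstraw",
                         significant_pcs = length(sig))

    coords <- embeddingCoords(pca)[, sig, drop = FALSE]
    clusters <- graphCluster(coords,
                             k_neighbors = min(k_neighbors, ncol(m) - 1),
                             resolution = resolution,
                             seed = .substream_seed(seed, "cluster"))
    cell_table$cluster <- clusters
    manifest <- logStage(manifest, "graph_cluster",
                         clusters = length(unique(clusters)))

    tsne <- NULL
    if (on("tsne") && ncol(m) > 3 * perplexity + 2) {
        tsne <- tsneBestOf(coords, n_runs = tsne_runs,
                           perplexity = perplexity,
                           seed = .substream_seed(seed, "tsne"))
        manifest <- logStage(manifest, "tsne",
                             kl = round(tsne@kl_divergence[1], 4))
    } else manifest <- logStage(manifest, "tsne", skipped = TRUE)

    markers <- NULL
    if (on("markers") && length(unique(clusters)) > 1) {
        markers <- aucMarkers(expr[hvg, , drop = FALSE], clusters)
        manifest <- logStage(manifest, "markers", rows = nrow(markers))
    } else manifest <- logStage(manifest, "markers", skipped = TRUE)

    sce <- SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(m, sparse = TRUE),
                      logcounts = expr),
        colData = DataFrame(cell_table, batch = batch,
                            row.names = colnames(m)))
    list(sce = sce, cell_table = cell_table, clusters = clusters,
         size_factors = sf, variable_genes = hvg, significant_pcs = sig,
         pca = pca, tsne = tsne, markers = markers, manifest = manifest)
}

#' Run the microfluidic (C1-style) co-expression + NMF consensus track
#'
#' Size-factor normalization and log2 transform, technical control genes
#' from the mean-variance trend with RUV-style factor removal, signed-hybrid
#' co-expression network with high-confidence edge pruning and dynamic tree
#' cut, then NMF consensus clustering of cells over module genes with rank
#' selection against a permuted-data control, AUC marker ranking, and
#' optional gene-set enrichment.
#'
#' @param counts SingleCellExperiment or genes-by-cells count matrix of QC-passed
#'   libraries.
#' @param rank_range surveyed NMF ranks.
#' @param n_runs NMF restarts per rank (50 is the reference setting).
#' @param beta soft power of the network (default 4).
#' @param hi_conf_expr,hi_conf_min_cells edge-pruning thresholds (6, 3).
#' @param deep_split,min_module_size tree-cut parameters (3, 30).
#' @param k_unwanted RUV factors to remove (default 1; 0 skips).
#' @param gene_sets optional named list for enrichment of top markers.
#' @param top_n markers kept per cluster (200).
#' @param run_control also survey permuted data as a rank-selection control.
#' @param nmf_max_iter iteration cap of the multiplicative updates.
#' @param seed integer seed.
#' @return list with \code{consensus} (a
#'   \linkS4class{ConsensusClustering}), \code{modules}, \code{markers},
#'   \code{enrichment}, \code{size_factors}, \code{control_genes} and the
#'   stage \code{manifest}.
#' @export
runC1Pipeline <- function(counts, rank_range = 2:8, n_runs = 50, beta = 4,
                          hi_conf_expr = 6, hi_conf_min_cells = 3,
                          deep_split = 3, min_module_size = 30,
                          k_unwanted = 1, gene_sets = NULL, top_n = 200,
                          run_control = TRUE, nmf_max_iter = 2000,
                          seed = 1L) {
    manifest <- list()
    m <- .as_dense(.get_counts(counts))
    sf <- pooledSizeFactors(m)
    expr <- logNormalize(m, sf)
    manifest <- logStage(manifest, "normalize", genes = nrow(expr),
                         cells = ncol(expr))

    ctrl <- selectControlGenes(expr)
    expr_ruv <- if (k_unwanted > 0 &&
                    length(ctrl$control_genes) >= k_unwanted)
        ruvRemove(expr, ctrl$control_genes, k_unwanted) else expr
    manifest <- logStage(manifest, "ruv",
                         control_genes = length(ctrl$control_genes),
                         k = k_unwanted)

    # biologically variable genes: variance above the mean-variance trend
    # (the complement of the technical control set)
    trend <- selectControlGenes(expr_ruv)$trend
    hvg <- rownames(expr_ruv)[!is.na(trend$fitted) &
                              trend$variance > trend$fitted]
    if (length(hvg) < 2 * min_module_size) {
        sds <- apply(expr_ruv, 1, sd)
        hvg <- rownames(expr_ruv)[order(-sds)[
            seq_len(min(nrow(expr_ruv), 10 * min_module_size))]]
    }
    ncounts <- sweep(.as_dense(m), 2, sf, "/")   # normalized count scale
    adj <- signedHybridAdjacency(expr_ruv[hvg, , drop = FALSE], beta = beta)
    dis <- confidencePrune(1 - adj, ncounts[hvg, , drop = FALSE],
                           hi_conf_expr, hi_conf_min_cells)
    mods <- dynamicTreeModules(dis, deep_split = deep_split,
                               min_module_size = min_module_size)
    manifest <- logStage(manifest, "network_modules",
                         genes = length(hvg),
                         modules = length(moduleSizes(mods)))
    mg <- moduleGenes(mods)
    if (!length(mg)) stop("stage network_modules: no modules detected")
    # factor removal can leave small negative values; NMF needs >= 0
    vmat <- pmax(expr_ruv[mg, , drop = FALSE], 0)

    ctrl_metrics <- data.frame()
    if (run_control) {
        perm <- permuteControl(vmat, seed = .substream_seed(seed, "perm"))
        ctrl_cc <- nmfConsensus(perm, rank_range = rank_range,
                                n_runs = n_runs, max_iter = nmf_max_iter,
                                seed = .substream_seed(seed, "nmfctrl"))
        ctrl_metrics <- rankMetrics(ctrl_cc)
        manifest <- logStage(manifest, "permuted_control",
                             ranks = length(rank_range))
    }
    cc <- nmfConsensus(vmat, rank_range = rank_range,
                       n_runs = n_runs, max_iter = nmf_max_iter,
                       seed = .substream_seed(seed, "nmf"),
                       control_metrics = ctrl_metrics)
    manifest <- logStage(manifest, "nmf_consensus",
                         chosen_rank = chosenRank(cc))

    markers <- aucMarkers(expr_ruv, consensusLabels(cc), top_n = top_n)
    manifest <- logStage(manifest, "markers", rows = nrow(markers))
    enrichment <- NULL
    if (!is.null(gene_sets)) {
        enrichment <- lapply(split(markers$gene, markers$cluster),
                             genesetEnrichment, gene_sets = gene_sets,
                             background = rownames(expr_ruv))
        manifest <- logStage(manifest, "enrichment",
                             clusters = length(enrichment))
    }
    list(consensus = cc, modules = mods, markers = markers,
         enrichment = enrichment, size_factors = sf,
         control_genes = ctrl$control_genes, expr = expr_ruv,
         manifest = manifest)
}

#' Run cross-species random-forest label transfer
#'
#' Filters the ortholog map to a high-identity one-to-one bijection,
#' translates both datasets onto the shared feature axis, balances the
#' training classes (down-sampling + SMOTE), optionally runs recursive
#' feature elimination, trains a forest on species A and evaluates it on
#' species B (confusion matrix, per-class recall and AUC), and reports
#' per-cluster marker-specificity correlation between species plus the
#' marker-overlap cross-tabulation.
#'
#' @param expr_A,expr_B genes-by-cells log-expression matrices.
#' @param labels_A,labels_B cluster labels per cell.
#' @param map ortholog data.frame.
#' @param min_identity ortholog identity floor (75).
#' @param run_rfe run recursive feature elimination before training.
#' @param ntree forest size (1000).
#' @param rfe_ntree,cv_folds RFE forest size and folds.
#' @param smote_k SMOTE neighbors (5).
#' @param seed integer seed.
#' @return list(bijection, model, transfer (confusion/auc on B), recall,
#'   specificity_correlation, marker_overlap, manifest).
#' @export
runCrossSpecies <- function(expr_A, labels_A, expr_B, labels_B, map,
                            min_identity = 75, run_rfe = TRUE, ntree = 1000,
                            rfe_ntree = 200, cv_folds = 10, smote_k = 5,
                            seed = 1L) {
    manifest <- list()
    bij <- filterOrthologs(map, min_identity = min_identity)
    bij <- bij[bij$gene_A %in% rownames(expr_A) &
               bij$gene_B %in% rownames(expr_B), , drop = FALSE]
    if (!nrow(bij)) stop("empty ortholog bijection after filtering")
    manifest <- logStage(manifest, "filter_orthologs", pairs = nrow(bij))

    xa <- t(expr_A[bij$gene_A, , drop = FALSE])
    xb <- t(expr_B[bij$gene_B, , drop = FALSE])
    colnames(xb) <- bij$gene_A   # shared feature axis named by species A

    bal <- balanceClasses(xa, labels_A, smote_k = smote_k,
                          seed = .substream_seed(seed, "smote"))
    manifest <- logStage(manifest, "balance_classes",
                         per_class = as.integer(table(bal$labels)[1]))

    feats <- colnames(xa)
    if (run_rfe) {
        p <- length(feats)
        schedule <- unique(pmax(2L, round(p / 2^(0:3))))
        rfe <- rfeSelect(bal$features, bal$labels,
                         sizes_schedule = schedule, cv_folds = cv_folds,
                         ntree = rfe_ntree,
                         seed = .substream_seed(seed, "rfe"))
        feats <- rfe$selected
        manifest <- logStage(manifest, "rfe_select", kept = length(feats))
    }
    model <- trainRf(bal$features[, feats, drop = FALSE], bal$labels,
                     ntree = ntree, seed = .substream_seed(seed, "rf"))
    manifest <- logStage(manifest, "train_rf",
                         oob = round(model$oob_error, 4))

    transfer <- classifyAndConfuse(model, xb, labels_B)
    recall <- diag(transfer$confusion[model$classes, model$classes,
                                      drop = FALSE])
    manifest <- logStage(manifest, "classify",
                         mean_recall = round(mean(recall), 3))

    spec_A <- featureSpecificity(t(xa), labels_A, feats)
    spec_B <- featureSpecificity(t(xb), labels_B, feats)
    common <- intersect(colnames(spec_A), colnames(spec_B))
    spec_cor <- specificityCorrelation(spec_A[, common, drop = FALSE],
                                       spec_B[, common, drop = FALSE])

    mk_A0 <- aucMarkers(expr_A, labels_A, top_n = 50)
    mk_A <- split(mk_A0$gene, mk_A0$cluster)
    mk_B0 <- aucMarkers(expr_B, labels_B, top_n = 50)
    # translate species-B markers through the bijection for the overlap test
    tr <- setNames(bij$gene_A, bij$gene_B)
    mk_B <- lapply(split(mk_B0$gene, mk_B0$cluster),
                   function(g) unname(tr[g[g %in% names(tr)]]))
    overlap <- markerOverlapTable(mk_A, mk_B, universe = bij$gene_A)

    list(bijection = bij, model = model, transfer = transfer,
         recall = recall, specificity_correlation = spec_cor,
         marker_overlap = overlap, manifest = manifest)
}
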