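test_that("normalized entropy matches closed forms", {
    expect_equal(normalizedEntropy(c(50, 50)), 1)
    expect_equal(normalizedEntropy(c(100, 0)), 0)
    expect_equal(round(normalizedEntropy(c(75, 25)), 4), 0.8113)
    expect_equal(normalizedEntropy(c(10)), 0)
})

test_that("batch entropy separates mixed batches from batch-driven structure", {
    set.seed(28)
    n <- 300
    cl <- rep(1:2, each = n / 2)
    coords <- cbind(rnorm(n, ifelse(cl == 1, 0, 12)), rnorm(n))
    rownames(coords) <- paste0("c", 1:n)
    batch <- sample(rep(c("b1", "b2"), n / 2))
    e <- batchEntropy(coords, batch, clusters = cl, n_locations = 50,
                      neighborhood_size = 50, n_boot = 25, seed = 5)
    # observed distribution overlaps the negative control; the positive
    # control sits strictly below both
    expect_gte(max(e$observed), quantile(e$negative_control, 0.05))
    expect_lte(min(e$observed), quantile(e$negative_control, 0.95))
    expect_lt(max(e$positive_control), min(e$negative_control))
    expect_error(batchEntropy(coords, rep("b1", n)), "2 batches")
})

test_that("pseudobulk is the within-group mean", {
    expr <- rbind(G1 = c(1, 3, 10), G2 = c(0, 2, 4))
    colnames(expr) <- paste0("c", 1:3)
    pb <- pseudobulk(expr, c("a", "a", "b"))
    expect_equal(pb[, "a"], c(G1 = 2, G2 = 1))
    expect_equal(pb[, "b"], c(G1 = 10, G2 = 4))
    expect_equal(as.integer(attr(pb, "group_sizes")), c(2L, 1L))
})

test_that("reference quantile normalization maps marginals exactly", {
    set.seed(29)
    m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("r", "s1", "s2")))
    qn <- quantileNormalizeToReference(m, "r")
    expect_equal(qn[, "r"], m[, "r"])
    for (j in 2:3) expect_equal(sort(qn[, j]), sort(m[, "r"]))
    # idempotent
    expect_equal(quantileNormalizeToReference(qn, "r"), qn)
    # hand-checked tie handling: ties map to the mean of tied positions
    m2 <- cbind(ref = c(1, 2, 9), x = c(5, 5, 7))
    q2 <- quantileNormalizeToReference(m2, "ref")
    expect_equal(unname(q2[, "x"]), c(1.5, 1.5, 9))
})

test_that("EB batch adjustment removes a planted shift", {
    set.seed(30)
    m <- matrix(rnorm(200 * 100, 5), 200, 100)
    rownames(m) <- paste0("G", 1:200)
    batch <- rep(c("b1", "b2"), each = 50)
    m[, batch == "b2"] <- m[, batch == "b2"] + 3
    adj <- ebBatchAdjust(m, batch)
    gd <- abs(rowMeans(adj[, batch == "b1"]) - rowMeans(adj[, batch == "b2"]))
    expect_lt(median(gd), 0.1)
    # grand means preserved within tolerance
    expect_lt(abs(mean(adj) - mean(m)), 0.05)
    # per-gene batch F statistic drops at least 5-fold in the median
    fstat <- function(mm) apply(mm, 1, function(y)
        summary(lm(y ~ batch))$fstatistic[1])
    expect_gt(median(fstat(m)) / median(fstat(adj)), 5)
    expect_warning(one <- ebBatchAdjust(m, rep("b1", 100)), "single batch")
    expect_identical(one, m)
})

test_that("complete-linkage trees merge the closest pair first", {
    m <- cbind(A = c(0, 0), B = c(1, 0), C = c(10, 0))
    rownames(m) <- c("f1", "f2")
    hc <- completeLinkageTree(m)
    first <- sort(hc$labels[-hc$merge[1, ]])
    expect_equal(first, c("A", "B"))
    # duplicated column merges at height zero
    m2 <- cbind(m, A2 = c(0, 0))
    expect_equal(min(completeLinkageTree(m2)$height), 0)
    d <- withr::local_tempdir()
    nwk <- file.path(d, "tree.nwk")
    completeLinkageTree(m, newick_path = nwk)
    expect_true(grepl("^\\(", readLines(nwk)[1]))
})

test_that("cluster-average trees report sensible node OOB errors", {
    set.seed(31)
    expr <- cbind(matrix(rnorm(50 * 60, 0), 50, 60),
                  matrix(rnorm(50 * 60, 5), 50, 60))
    rownames(expr) <- paste0("G", 1:50)
    colnames(expr) <- paste0("c", 1:120)
    labels <- rep(c("x", "y"), each = 60)
    res <- clusterMeanTree(expr, labels, ntree = 100, seed = 2)
    expect_equal(length(res$tree$labels), 2)
    expect_lt(res$node_oobe$oob_error[1], 0.05)

    # indistinguishable clusters give ~50% error at the root
    expr2 <- matrix(rnorm(50 * 120), 50, 120,
                    dimnames = dimnames(expr))
    res2 <- clusterMeanTree(expr2, labels, ntree = 100, seed = 2)
    expect_gt(res2$node_oobe$oob_error[1], 0.3)
})

test_that("composition summaries detect a planted expansion", {
    set.seed(32)
    make_rep <- function(fr, n = 300)
        sample(rep(seq_along(fr), diff(round(cumsum(c(0, fr)) * n))))
    fr_a <- c(0.34, 0.33, 0.33)
    fr_b <- c(0.47, 0.265, 0.265)
    labels <- c(unlist(lapply(1:3, function(i) make_rep(fr_a))),
                unlist(lapply(1:3, function(i) make_rep(fr_b))))
    sample_ids <- rep(paste0("r", 1:6), each = 300)
    condition <- rep(c("ctrl", "dss"), each = 3 * 300)
    cs <- compositionSummary(labels, sample_ids, condition)
    expect_equal(unname(rowSums(cs$fractions)), rep(1, 6), tolerance = 1e-12)
    expect_equal(cs$table$cluster[which.min(cs$table$p_value)], "1")
    # identical compositions: no signal
    cs0 <- compositionSummary(rep(1:3, 600), rep(paste0("r", 1:6), 300),
                              rep(c("a", "b"), each = 900))
    expect_true(all(cs0$table$p_value > 0.9))
    expect_error(compositionSummary(labels, sample_ids,
                                    rep("one", length(labels))),
                 "2 conditions")
})
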