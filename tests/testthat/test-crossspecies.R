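test_that("ortholog filter yields exactly the planted high-identity bijection", {
    map <- toy_ortholog_map()
    bij <- filterOrthologs(map, min_identity = 75)
    # one2one rows with min identity >= 75: A1 (88), A2 (80), A3 (75)
    expect_setequal(bij$gene_A, c("A1", "A2", "A3"))
    expect_false("A4" %in% bij$gene_A)    # 74.9 fails the floor
    expect_false(any(c("A7", "A8", "A9") %in% bij$gene_A))
    # bijection: no duplicated genes; applying twice is the identity
    expect_false(anyDuplicated(bij$gene_A) > 0)
    expect_false(anyDuplicated(bij$gene_B) > 0)
    map2 <- data.frame(gene_A = bij$gene_A, gene_B = bij$gene_B,
                       homology_class = "one2one",
                       pct_identity_AtoB = 90, pct_identity_BtoA = 90)
    expect_equal(filterOrthologs(map2)$gene_A, bij$gene_A)
})

test_that("class balancing equalizes counts and SMOTE interpolates", {
    set.seed(19)
    x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(10, 5), 5, 2))
    rownames(x) <- paste0("c", 1:25)
    colnames(x) <- c("f1", "f2")
    y <- rep(c("big", "small"), c(20, 5))
    bal <- balanceClasses(x, y, target_per_class = 12, smote_k = 3, seed = 2)
    expect_true(all(table(bal$labels) == 12))
    # synthetic points lie within the minority bounding box (on segments)
    syn <- bal$features[grepl("^synthetic", rownames(bal$features)), ,
                        drop = FALSE]
    mins <- apply(x[21:25, ], 2, min); maxs <- apply(x[21:25, ], 2, max)
    expect_true(all(t(syn) >= mins - 1e-12 & t(syn) <= maxs + 1e-12))

    # two-point minority with k = 1: synthetic points on the segment
    x2 <- rbind(matrix(rnorm(40), 20, 2), c(0, 0), c(1, 1))
    rownames(x2) <- paste0("c", 1:22)
    y2 <- rep(c("a", "b"), c(20, 2))
    bal2 <- suppressWarnings(
        balanceClasses(x2, y2, target_per_class = 6, smote_k = 1, seed = 3))
    syn2 <- bal2$features[grepl("^synthetic", rownames(bal2$features)), ]
    expect_equal(syn2[, 1], syn2[, 2])   # on y = x
    expect_true(all(syn2 >= 0 & syn2 <= 1))

    # identical minority points only produce themselves
    x3 <- rbind(matrix(rnorm(20), 10, 2), c(2, 2), c(2, 2))
    rownames(x3) <- paste0("c", 1:12)
    bal3 <- suppressWarnings(balanceClasses(x3, rep(c("a", "b"), c(10, 2)),
                                            target_per_class = 5,
                                            smote_k = 1, seed = 1))
    syn3 <- bal3$features[grepl("^synthetic", rownames(bal3$features)), ]
    expect_true(all(syn3 == 2))

    expect_error(balanceClasses(x3, rep(c("a", "b"), c(11, 1))), "2 members")
})

test_that("forest training is deterministic with recorded mtry", {
    set.seed(20)
    x <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 4), 100, 2))
    colnames(x) <- c("f1", "f2")
    y <- rep(c("a", "b"), each = 100)
    m1 <- trainRf(x, y, ntree = 100, seed = 5)
    m2 <- trainRf(x, y, ntree = 100, seed = 5)
    expect_lt(m1$oob_error, 0.05)
    expect_identical(predict(m1$forest, x), predict(m2$forest, x))
    xp <- matrix(rnorm(200 * 100), 200, 100,
                 dimnames = list(NULL, paste0("f", 1:100)))
    expect_equal(trainRf(xp, y, ntree = 20, seed = 1)$params$mtry, 10)
    expect_error(trainRf(x, rep("a", 200)), "2 classes")
})

test_that("recursive feature elimination keeps informative features", {
    set.seed(21)
    n <- 90
    y <- factor(rep(c("a", "b", "c"), each = n / 3))
    informative <- vapply(1:5, function(i)
        as.numeric(y) * 2 + rnorm(n, sd = 0.4), numeric(n))
    noise <- matrix(rnorm(n * 100), n, 100)
    x <- cbind(informative, noise)
    colnames(x) <- c(paste0("inf", 1:5), paste0("noise", 1:100))
    sel <- rfeSelect(x, y, sizes_schedule = c(105, 50, 10, 5),
                     cv_folds = 5, ntree = 100, seed = 2)
    expect_true(all(paste0("inf", 1:5) %in% sel$selected))
    expect_lte(length(sel$selected), 10)

    # one-size schedule returns everything
    all_feats <- rfeSelect(x[, 1:8], y, sizes_schedule = 8, cv_folds = 5,
                           ntree = 50, seed = 1)
    expect_length(all_feats$selected, 8)
    expect_error(rfeSelect(x[1:3, ], y[1:3], 5, cv_folds = 10), "folds")
})

test_that("classification reports normalized confusion and AUC", {
    set.seed(22)
    x <- rbind(matrix(rnorm(300, 0), 150, 2), matrix(rnorm(300, 4), 150, 2))
    colnames(x) <- c("f1", "f2")
    y <- rep(c("a", "b"), each = 150)
    model <- trainRf(x, y, ntree = 100, seed = 4)
    res <- classifyAndConfuse(model, x, y)
    expect_equal(unname(rowSums(res$confusion)), c(1, 1))
    expect_gt(min(diag(res$confusion)), 0.95)
    expect_gt(min(res$auc), 0.95)
    expect_error(classifyAndConfuse(model, x[, 1, drop = FALSE], y),
                 "lacks model features")
})

test_that("feature specificity scores behave at the extremes", {
    labels <- rep(c("a", "b"), each = 10)
    expr <- rbind(CONST = rep(1, 20),
                  EXCL = c(rep(5, 10), rep(0, 10)))
    colnames(expr) <- paste0("c", 1:20)
    sp <- featureSpecificity(expr, labels)
    expect_equal(unname(sp["CONST", ]), c(0.5, 0.5))
    expect_equal(unname(sp["EXCL", "a"]), 1)
    expect_lt(sp["EXCL", "b"], 0.5)
    expect_equal(unname(specificityCorrelation(sp, sp)), c(1, 1))
})
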