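test_that("marker AUC equals brute-force pair counting", {
    x <- c(1, 2, 3, 4)
    pos <- c(FALSE, FALSE, TRUE, TRUE)
    expect_equal(aucRank(x, pos), 1)
    expect_equal(aucRank(c(1, 2, 2, 4), pos), 0.875)
    expect_equal(aucRank(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)

    set.seed(14)
    for (i in 1:50) {
        n <- sample(6:20, 1)
        x <- sample(0:5, n, replace = TRUE)   # many ties
        pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(pos) || all(pos)) next
        expect_identical(aucRank(x, pos), auc_brute(x, pos))
    }
    # AUC of a gene and its negation sum to 1
    x <- rnorm(30); pos <- rep(c(TRUE, FALSE), 15)
    expect_equal(aucRank(x, pos) + aucRank(-x, pos), 1)
    # invariance to monotone transforms
    expect_equal(aucRank(exp(x), pos), aucRank(x, pos))
})

test_that("aucMarkers targets the highest-mean cluster and ranks by AUC", {
    set.seed(15)
    labels <- rep(c("A", "B"), each = 20)
    expr <- rbind(
        ONLY_A = c(rexp(20) + 2, rep(0, 20)),
        FLAT = rnorm(40, 5, 0.01))
    expr <- rbind(expr, matrix(rnorm(40 * 5), 5, 40,
                               dimnames = list(paste0("N", 1:5), NULL)))
    colnames(expr) <- paste0("c", 1:40)
    tab <- aucMarkers(expr, labels, top_n = 3)
    only_a <- tab[tab$gene == "ONLY_A", ]
    expect_equal(only_a$cluster, "A")
    expect_equal(only_a$auc, 1)
    expect_true(all(table(tab$cluster) <= 3))
})

test_that("filtered markers honor detection and fold-change gates", {
    set.seed(16)
    n <- 60
    labels <- rep(c("A", "B"), each = n / 2)
    expr <- rbind(
        RARE = ifelse(runif(n) < 0.1, 3, 0),            # 10% detection
        MARK = c(rnorm(n / 2, 4, 0.3), rnorm(n / 2, 0.2, 0.1)))
    colnames(expr) <- paste0("c", 1:n)
    out <- filteredMarkers(expr, labels, cluster = "A")
    expect_false("RARE" %in% out$gene)
    expect_true("MARK" %in% out$gene)
    # empty result when nothing is expressed
    zero <- matrix(0, 2, n, dimnames = list(c("Z1", "Z2"), paste0("c", 1:n)))
    expect_equal(nrow(filteredMarkers(zero, labels)), 0)
})

test_that("NB GLM is calibrated under the null and recovers planted effects", {
    set.seed(17)
    n <- 300
    grp <- factor(rep(c("A", "B"), each = n / 2))
    sf <- exp(rnorm(n, 0, 0.3)); sf <- sf / mean(sf)
    mu0 <- exp(runif(800, log(1), log(50)))
    null_counts <- t(vapply(mu0, function(m0)
        rnbinom(n, mu = m0 * sf, size = 1 / 0.3), numeric(n)))
    rownames(null_counts) <- paste0("g", seq_len(nrow(null_counts)))
    de0 <- nbGlmDe(null_counts, grp, size_factors = sf)
    expect_gt(mean(de0$p_value < 0.05, na.rm = TRUE), 0.02)
    expect_lt(mean(de0$p_value < 0.05, na.rm = TRUE), 0.08)

    mu1 <- exp(runif(200, log(2), log(50)))
    alt <- t(vapply(mu1, function(m0)
        rnbinom(n, mu = m0 * sf * ifelse(grp == "B", 2, 1), size = 1 / 0.2),
        numeric(n)))
    rownames(alt) <- paste0("h", seq_len(nrow(alt)))
    de1 <- nbGlmDe(alt, grp, size_factors = sf)
    expect_gt(median(de1$log2_fc, na.rm = TRUE), 0.8)
    expect_lt(median(de1$log2_fc, na.rm = TRUE), 1.2)

    # all-zero genes are excluded, BH is monotone in the threshold
    withzero <- rbind(alt[1:5, ], ZERO = rep(0L, n))
    dez <- nbGlmDe(withzero, grp, size_factors = sf)
    expect_false("ZERO" %in% dez$gene)
    expect_lte(sum(de0$p_adj < 0.01, na.rm = TRUE),
               sum(de0$p_adj < 0.05, na.rm = TRUE))
})

test_that("NB GLM approaches Poisson results on Poisson data", {
    set.seed(18)
    n <- 200
    grp <- factor(rep(c("A", "B"), each = n / 2))
    y <- rpois(n, ifelse(grp == "B", 20, 10))
    m <- matrix(y, 1, n, dimnames = list("g1", NULL))
    de <- nbGlmDe(m, grp, size_factors = rep(1, n))
    pf <- glm(y ~ grp, family = poisson())
    expect_lt(abs(de$log_fc - coef(pf)["grpB"]), 1e-3)
})

test_that("hypergeometric enrichment equals direct summation", {
    universe <- paste0("G", 1:100)
    sets <- list(S = paste0("G", 1:10))
    query <- paste0("G", c(1:5, 50:54))     # overlap 5, |query| = 10
    out <- genesetEnrichment(query, sets, universe)
    expect_equal(out$p_value, hyper_brute(5, 10, 10, 100), tolerance = 1e-12)
    expect_equal(out$overlap, 5)
    # disjoint query finds nothing
    out2 <- genesetEnrichment(paste0("G", 90:99),
                              list(S = paste0("G", 1:10)), universe)
    expect_false(any(out2$significant))
    expect_error(genesetEnrichment(query, sets, character()), "background")
})

test_that("marker overlap tables agree with the hypergeometric oracle", {
    universe <- paste0("G", 1:100)
    A <- list(c1 = paste0("G", 1:10))
    B <- list(c1 = paste0("G", c(1:5, 60:64)),
              c2 = paste0("G", 80:89))
    ov <- markerOverlapTable(A, B, universe)
    expect_equal(ov$shared["c1", "c1"], 5)
    expect_equal(ov$shared["c1", "c2"], 0)
    expect_equal(ov$p["c1", "c1"], hyper_brute(5, 10, 10, 100),
                 tolerance = 1e-10)
    expect_gt(ov$p["c1", "c2"], 0.5)
    # identical sets give the minimal p in their row
    ident <- markerOverlapTable(A, A, universe)
    expect_equal(ident$shared["c1", "c1"], 10)
    expect_lt(ident$p["c1", "c1"], 1e-10)
})
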