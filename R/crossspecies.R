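#' Filter an ortholog map to a high-identity one-to-one bijection
#'
#' Keeps only one2one rows whose available percent identities (both
#' directions when present) are at least \code{min_identity}, then enforces
#' a bijection by dropping any gene still appearing more than once.
#'
#' @param map ortholog data.frame (see \code{\link{validateOrthologMap}}).
#' @param min_identity minimum percent sequence identity (default 75).
#' @return data.frame with columns gene_A, gene_B forming a bijection.
#' @export
filterOrthologs <- function(map, min_identity = 75) {
    validateOrthologMap(map)
    keep <- map$homology_class == "one2one"
    idmin <- pmin(ifelse(is.na(map$pct_identity_AtoB), Inf,
                         map$pct_identity_AtoB),
                  ifelse(is.na(map$pct_identity_BtoA), Inf,
                         map$pct_identity_BtoA))
    keep <- keep & idmin >= min_identity & is.finite(idmin)
    out <- map[keep, c("gene_A", "gene_B"), drop = FALSE]
    out <- out[!(out$gene_A %in% out$gene_A[duplicated(out$gene_A)]) &
               !(out$gene_B %in% out$gene_B[duplicated(out$gene_B)]), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Balance classes by down-sampling and SMOTE up-sampling
#'
#' Majority classes are down-sampled without replacement to the target;
#' minority classes are up-sampled by SMOTE: each synthetic observation is
#' x + lambda (x_nn - x) with lambda ~ U(0,1) and x_nn one of the k nearest
#' same-class neighbors (Euclidean) of a randomly chosen real member.
#'
#' @param features cells-by-features numeric matrix.
#' @param labels class label per cell (every class >= 2 members).
#' @param target_per_class target size (default: median class size).
#' @param smote_k SMOTE neighbor count (default 5; clamped with a warning
#'   when a class is smaller).
#' @param seed integer seed.
#' @return list(features, labels) with exactly target_per_class per class;
#'   synthetic rows are named "synthetic.N".
#' @export
balanceClasses <- function(features, labels, target_per_class = NULL,
                           smote_k = 5, seed = 1L) {
    labels <- as.character(labels)
    tab <- table(labels)
    if (any(tab < 2L)) stop("every class needs at least 2 members for SMOTE")
    if (is.null(target_per_class))
        target_per_class <- as.integer(round(median(tab)))
    set.seed(seed)
    out_x <- list(); out_y <- list(); syn_i <- 0L
    for (k in names(tab)) {
        ix <- which(labels == k)
        if (length(ix) >= target_per_class) {
            sel <- if (length(ix) == target_per_class) ix else
                sample(ix, target_per_class)
            out_x[[k]] <- features[sel, , drop = FALSE]
        } else {
            kk <- smote_k
            if (kk >= length(ix)) {
                kk <- length(ix) - 1L
                warning("class ", k, ": smote_k clamped to ", kk)
            }
            xs <- features[ix, , drop = FALSE]
            d <- as.matrix(dist(xs)); diag(d) <- Inf
            nnb <- matrix(0L, length(ix), kk)
            for (r in seq_along(ix)) nnb[r, ] <- order(d[r, ])[seq_len(kk)]
            n_syn <- target_per_class - length(ix)
            syn <- matrix(NA_real_, n_syn, ncol(features))
            for (s in seq_len(n_syn)) {
                i <- sample(length(ix), 1L)
                j <- nnb[i, sample(kk, 1L)]
                lam <- runif(1)
                syn[s, ] <- xs[i, ] + lam * (xs[j, ] - xs[i, ])
            }
            rownames(syn) <- paste0("synthetic.", syn_i + seq_len(n_syn))
            syn_i <- syn_i + n_syn
            colnames(syn) <- colnames(features)
            out_x[[k]] <- rbind(xs, syn)
        }
        out_y[[k]] <- rep(k, target_per_class)
    }
    list(features = do.call(rbind, out_x),
         labels = factor(unlist(out_y, use.names = FALSE)))
}

#' Train a random forest classifier
#'
#' ntree trees with mtry = floor(sqrt(p)); seed-deterministic; out-of-bag
#' error is recorded in the model metadata.
#'
#' @param features cells-by-features matrix.
#' @param labels class label per cell (>= 2 classes).
#' @param ntree number of trees (default 1000).
#' @param seed integer seed.
#' @return list(forest, features, classes, oob_error, params).
#' @export
trainRf <- function(features, labels, ntree = 1000, seed = 1L) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) < 2L) stop("need at least 2 classes")
    mtry <- max(1L, floor(sqrt(ncol(features))))
    set.seed(seed)
    fit <- randomForest::randomForest(x = features, y = labels,
                                      ntree = ntree, mtry = mtry)
    list(forest = fit,
         features = colnames(features),
         classes = levels(labels),
         oob_error = unname(fit$err.rate[ntree, "OOB"]),
         params = list(ntree = ntree, mtry = mtry, seed = seed))
}

#' Recursive feature elimination with cross-validated size selection
#'
#' Features are ranked by impurity importance from a forest on the full
#' feature set and iteratively reduced along \code{sizes_schedule}; each
#' size is scored by k-fold cross-validated accuracy. The selected size is
#' the smallest whose mean accuracy is within one standard deviation of the
#' best, and the top-ranked features at that size are returned.
#'
#' @param features cells-by-features matrix.
#' @param labels class label per cell.
#' @param sizes_schedule decreasing feature-set sizes to evaluate.
#' @param cv_folds folds (default 10; must not exceed cells).
#' @param ntree trees per forest (default 1000).
#' @param seed integer seed.
#' @return list(selected = feature names, cv = data.frame(size, accuracy,
#'   sd)).
#' @export
rfeSelect <- function(features, labels, sizes_schedule, cv_folds = 10,
                      ntree = 1000, seed = 1L) {
    labels <- droplevels(as.factor(labels))
    n <- nrow(features)
    if (n < cv_folds) stop("fewer cells than folds")
    stopifnot(!is.unsorted(rev(sizes_schedule)),
              max(sizes_schedule) <= ncol(features))
    set.seed(seed)
    folds <- sample(rep_len(seq_len(cv_folds), n))
    rank_feats <- function(x, y) {
        f <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                        mtry = max(1L, floor(sqrt(ncol(x)))))
        imp <- randomForest::importance(f)[, 1]
        names(sort(imp, decreasing = TRUE))
    }
    ranking <- rank_feats(features, labels)
    cv <- data.frame(size = sizes_schedule, accuracy = NA_real_,
                     sd = NA_real_)
    kept <- list()
    for (si in seq_along(sizes_schedule)) {
        sz <- sizes_schedule[si]
        feats <- ranking[seq_len(sz)]
        kept[[si]] <- feats
        acc <- vapply(seq_len(cv_folds), function(fo) {
            tr <- folds != fo
            fit <- randomForest::randomForest(
                x = features[tr, feats, drop = FALSE], y = labels[tr],
                ntree = ntree, mtry = max(1L, floor(sqrt(sz))))
            mean(predict(fit, features[!tr, feats, drop = FALSE]) ==
                 labels[!tr])
        }, numeric(1))
        cv$accuracy[si] <- mean(acc)
        cv$sd[si] <- sd(acc)
        # re-rank within the surviving features for the next, smaller size
        if (si < length(sizes_schedule))
            ranking <- rank_feats(features[, feats, drop = FALSE], labels)
    }
    best <- which.max(cv$accuracy)
    ok <- cv$accuracy >= cv$accuracy[best] - cv$sd[best]
    pick <- which(cv$size == min(cv$size[ok]))[1]
    list(selected = kept[[pick]], cv = cv)
}

#' Classify cells and summarize the confusion structure
#'
#' Predicts labels for a query matrix (re-indexed to the model's features,
#' via an ortholog bijection upstream for cross-species use), and reports
#' the row-normalized confusion matrix (each true class sums to 1) plus
#' one-vs-rest AUC per class computed from the forest's vote fractions.
#'
#' @param model result of \code{\link{trainRf}}.
#' @param features query cells-by-features matrix; must contain all model
#'   features.
#' @param true_labels known labels of the query cells.
#' @return list(predicted, confusion, auc).
#' @export
classifyAndConfuse <- function(model, features, true_labels) {
    miss <- setdiff(model$features, colnames(features))
    if (length(miss))
        stop("query lacks model features: ",
             paste(head(miss, 5), collapse = ", "),
             if (length(miss) > 5) " ..." else "")
    x <- features[, model$features, drop = FALSE]
    pred <- predict(model$forest, x)
    votes <- predict(model$forest, x, type = "prob")
    true_labels <- factor(as.character(true_labels))
    conf <- table(true = true_labels, predicted = factor(pred,
                  levels = model$classes))
    conf <- sweep(conf, 1, pmax(rowSums(conf), 1), "/")
    auc <- vapply(model$classes, function(k)
        aucRank(votes[, k], as.character(true_labels) == k), numeric(1))
    list(predicted = pred, confusion = as.matrix(conf), auc = auc)
}

#' Per-feature cluster specificity scores
#'
#' For each feature and cluster, the one-vs-rest AUC of the feature for that
#' cluster: 1 marks an exclusive positive marker, 0.5 a non-specific gene,
#' values below 0.5 negative markers.
#'
#' @param expr genes-by-cells expression matrix.
#' @param labels cluster label per cell.
#' @param features features (genes) to score.
#' @return features-by-clusters matrix of AUC scores in [0,1].
#' @export
featureSpecificity <- function(expr, labels, features = rownames(expr)) {
    labels <- as.character(labels)
    ulab <- sort(unique(labels))
    out <- matrix(NA_real_, length(features), length(ulab),
                  dimnames = list(features, ulab))
    for (k in ulab) {
        pos <- labels == k
        out[, k] <- vapply(features, function(g) {
            a <- aucRank(expr[g, ], pos)
            if (is.na(a)) 0.5 else a
        }, numeric(1))
    }
    out
}

#' Correlation of marker specificity between species
#'
#' Per cluster, the Pearson correlation between two species' feature
#' specificity vectors over shared (ortholog-translated) features.
#'
#' @param spec_A,spec_B features-by-clusters specificity matrices with
#'   matching dimnames (features already translated to a common axis).
#' @return Named numeric vector, one correlation per cluster.
#' @export
specificityCorrelation <- function(spec_A, spec_B) {
    stopifnot(identical(dimnames(spec_A), dimnames(spec_B)))
    vapply(colnames(spec_A), function(k) {
        a <- spec_A[, k]; b <- spec_B[, k]
        if (sd(a) == 0 && sd(b) == 0) return(1)
        if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
        cor(a, b)
    }, numeric(1))
}
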