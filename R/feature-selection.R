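makeRanking <- function(method, scores) {
    ord <- order(-scores, seq_along(scores))
    new("FeatureRanking", method = method, scores = scores,
        order = as.integer(ord))
}

#' Chi-squared feature ranking
#'
#' The standard nonnegative-feature chi-squared selection statistic: for
#' each feature, the observed class-conditional feature sums are compared
#' with expected sums proportional to the class frequencies, and the
#' chi-squared statistic sum((O - E)^2 / E) over the two classes is the
#' score.  Constant-zero expectation terms contribute 0, so constant
#' features score 0.  Apply min-max normalization first: the statistic is
#' defined for nonnegative features only.
#'
#' @param data a two-class \linkS4class{LabeledDataset} with nonnegative
#'   features.
#' @return A \linkS4class{FeatureRanking} with method "chi2".
#' @export
chi2Rank <- function(data) {
    stopIfMissingValues(data, "chi-squared ranking")
    stopIfSingleClass(data, "chi-squared ranking")
    if (any(data@features < 0))
        stop("chi-squared ranking requires nonnegative features; ",
             "min-max normalize first", call. = FALSE)
    n <- nSamples(data)
    classes <- c(0L, 1L)
    freq <- vapply(classes, function(cl) sum(data@labels == cl), numeric(1)) / n
    obs <- vapply(classes, function(cl)
        colSums(data@features[data@labels == cl, , drop = FALSE]),
        numeric(nFeatures(data)))
    obs <- matrix(obs, ncol = 2)
    total <- rowSums(obs)
    scores <- numeric(nFeatures(data))
    for (c in 1:2) {
        e <- freq[c] * total
        term <- ifelse(e > 0, (obs[, c] - e)^2 / e, 0)
        scores <- scores + term
    }
    names(scores) <- featNames(data)
    makeRanking("chi2", scores)
}

# weight vector of a fitted linear SVM: w = t(coefs) %*% SV
linearSvmWeights <- function(x, y) {
    fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "linear",
                      cost = 1, scale = FALSE)
    drop(crossprod(fit$coefs, fit$SV))
}

#' Recursive feature elimination with a linear SVM
#'
#' Repeatedly fits a linear support-vector classifier (C = 1) and removes
#' the \code{step} features with the smallest squared weights until none
#' remain; the score of a feature is its elimination position (the last
#' survivors score highest, ordered by the final fit's weight magnitudes).
#' Deterministic, and invariant to sample order.
#'
#' @param data a two-class \linkS4class{LabeledDataset}.
#' @param step number of features removed per round; must be smaller than
#'   the number of features.
#' @return A \linkS4class{FeatureRanking} with method "rfe_svc".
#' @export
rfeSvcRank <- function(data, step = 1L) {
    stopIfMissingValues(data, "RFE ranking")
    stopIfSingleClass(data, "RFE ranking")
    step <- as.integer(step)
    p <- nFeatures(data)
    if (step < 1L || step >= p)
        stop("step must be in [1, n_features - 1]", call. = FALSE)
    remaining <- seq_len(p)
    scores <- numeric(p)
    names(scores) <- featNames(data)
    counter <- 0L
    while (length(remaining) > step) {
        w2 <- linearSvmWeights(data@features[, remaining, drop = FALSE],
                               data@labels)^2
        drop_local <- order(w2, remaining)[seq_len(step)]
        # eliminated features get increasing scores; smallest weight first
        for (d in drop_local) {
            counter <- counter + 1L
            scores[remaining[d]] <- counter
        }
        remaining <- remaining[-drop_local]
    }
    # final fit ranks the survivors by weight magnitude
    w2 <- linearSvmWeights(data@features[, remaining, drop = FALSE],
                           data@labels)^2
    for (d in order(w2, remaining)) {
        counter <- counter + 1L
        scores[remaining[d]] <- counter
    }
    makeRanking("rfe_svc", scores)
}

#' Gradient-boosted-tree importance ranking
#'
#' Trains a gradient-boosted decision-tree classifier (100 rounds, depth 3,
#' learning rate 0.1, single thread, fixed seed) and scores each feature by
#' its gain-based importance; features never used by a split score 0.
#'
#' @param data a two-class \linkS4class{LabeledDataset}.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta booster hyperparameters.
#' @return A \linkS4class{FeatureRanking} with method "boostfs".
#' @export
boostfsRank <- function(data, seed = 1L, nrounds = 100L, max_depth = 3L,
                        eta = 0.1) {
    stopIfMissingValues(data, "boosted ranking")
    stopIfSingleClass(data, "boosted ranking")
    booster <- withSeed(seed, {
        dtrain <- xgboost::xgb.DMatrix(data@features,
                                       label = data@labels, nthread = 1)
        xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          max_depth = as.integer(max_depth), eta = eta,
                          nthread = 1, seed = as.integer(seed)),
            data = dtrain, nrounds = as.integer(nrounds))
    })
    imp <- xgboost::xgb.importance(model = booster)
    scores <- stats::setNames(numeric(nFeatures(data)), featNames(data))
    if (nrow(imp)) scores[imp$Feature] <- imp$Gain
    makeRanking("boostfs", scores)
}

#' Restrict a dataset to the top-ranked features
#'
#' Keeps the \code{n_keep} best features of a ranking; the kept features
#' stay in their original column order.
#'
#' @param ranking a \linkS4class{FeatureRanking}.
#' @param data the \linkS4class{LabeledDataset} the ranking refers to.
#' @param n_keep number of features to keep (<= n_features).
#' @return The restricted \linkS4class{LabeledDataset}.
#' @export
applyCutoff <- function(ranking, data, n_keep) {
    n_keep <- as.integer(n_keep)
    if (n_keep < 1L || n_keep > nFeatures(data))
        stop("n_keep must be in [1, n_features]", call. = FALSE)
    if (length(ranking@scores) != nFeatures(data))
        stop("ranking does not match the dataset's features", call. = FALSE)
    keep <- sort(ranking@order[seq_len(n_keep)])
    data[, keep]
}

#' Sweep feature-count cut-offs and score the default ensemble
#'
#' For each cut-off in the grid, restricts train and test to the top-ranked
#' features, fits the default voting ensemble on the restricted training
#' set, and records test accuracy and AUC.  Grid entries above the feature
#' count are clipped and deduplicated.
#'
#' @param ranking a \linkS4class{FeatureRanking} fitted on \code{train}.
#' @param train,test \linkS4class{LabeledDataset} splits sharing features.
#' @param grid integer cut-offs (default 5, 10, ..., 1000, clipped).
#' @param rounds,k,seed,resample_first passed to \code{\link{fitEnsemble}}.
#' @return data.frame with columns cutoff, accuracy, auc.
#' @export
sweepCutoffs <- function(ranking, train, test,
                         grid = seq(5L, 1000L, by = 5L), rounds = 10L,
                         k = 3L, seed = 1L, resample_first = TRUE) {
    if (!length(grid)) stop("empty cut-off grid", call. = FALSE)
    grid <- sort(unique(pmin(as.integer(grid), nFeatures(train))))
    rows <- lapply(grid, function(nk) {
        tr <- applyCutoff(ranking, train, nk)
        te <- applyCutoff(ranking, test, nk)
        ens <- fitEnsemble(tr, rounds = rounds, resample_first = resample_first,
                           k = k, seed = seed)
        rep <- evaluateModel(ens, te)
        data.frame(cutoff = nk, accuracy = rep@accuracy, auc = rep@auc)
    })
    do.call(rbind, rows)
}

# vectorized Welch two-sample t-test (condition vs reference), two-sided
welchT <- function(cond, ref) {
    n1 <- nrow(cond); n0 <- nrow(ref)
    m1 <- colMeans(cond); m0 <- colMeans(ref)
    v1 <- apply(cond, 2, stats::var); v0 <- apply(ref, 2, stats::var)
    se2 <- v1 / n1 + v0 / n0
    tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2),
                    ifelse(m1 == m0, 0, Inf * sign(m1 - m0)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
                 1)
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!is.finite(tstat)] <- 0
    p[tstat == 0] <- 1
    list(effect = m1 - m0, p = p)
}

#' Three-contrast differential-expression gene selection
#'
#' For each of three contrasts (typically control-vs-patient,
#' baseline-vs-year1 and year1-vs-year2), performs a per-gene Welch
#' two-sample t-test of the condition group (label 1) against the reference
#' group (label 0), adjusts p-values across genes within the contrast by
#' Benjamini-Hochberg, and calls a gene DE when the adjusted p falls below
#' \code{alpha}.  Direction is the sign of the condition-minus-reference
#' mean difference ("up" when positive).  The intersections collect genes
#' DE with a consistent direction in all three contrasts.
#'
#' @param stages named list of three \linkS4class{LabeledDataset} contrasts
#'   with identical feature names; in each, label 0 is the reference group
#'   and label 1 the condition group.
#' @param alpha threshold on BH-adjusted p (default 0.005).
#' @param log_transform if TRUE, values are log2(x + 1)-transformed before
#'   testing (for raw-scale expression).
#' @return A \linkS4class{DEGResult}.
#' @export
selectDegs <- function(stages, alpha = 0.005, log_transform = FALSE) {
    if (length(stages) != 3L)
        stop("exactly three contrasts are required", call. = FALSE)
    if (is.null(names(stages)))
        names(stages) <- c("control_vs_patient", "baseline_vs_year1",
                           "year1_vs_year2")
    genes <- featNames(stages[[1]])
    for (s in stages) {
        if (!identical(featNames(s), genes))
            stop("feature names must match across contrasts", call. = FALSE)
        counts <- table(factor(s@labels, levels = c(0L, 1L)))
        if (any(counts < 2L))
            stop("each contrast needs >= 2 samples per group", call. = FALSE)
    }
    per_contrast <- lapply(stages, function(s) {
        mat <- s@features
        if (log_transform) mat <- log2(mat + 1)
        res <- welchT(mat[s@labels == 1L, , drop = FALSE],
                      mat[s@labels == 0L, , drop = FALSE])
        adj <- stats::p.adjust(res$p, method = "BH")
        dirn <- ifelse(res$effect > 0, "up",
                       ifelse(res$effect < 0, "down", "none"))
        data.frame(gene = genes, effect = res$effect, p = res$p,
                   adj_p = adj,
                   direction = dirn,
                   de = adj < alpha & dirn != "none",
                   stringsAsFactors = FALSE, row.names = NULL)
    })
    up_sets <- lapply(per_contrast, function(pc)
        pc$gene[pc$de & pc$direction == "up"])
    down_sets <- lapply(per_contrast, function(pc)
        pc$gene[pc$de & pc$direction == "down"])
    new("DEGResult", per_contrast = per_contrast,
        intersection_up = Reduce(intersect, up_sets),
        intersection_down = Reduce(intersect, down_sets),
        alpha = alpha)
}
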