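# ---- plain baseline learners for the benchmark harness ------------------

#' Fit a plain (unboosted, unbalanced) baseline classifier
#'
#' The comparison points of the benchmark harness: a 100-tree random
#' forest, an RBF-kernel SVM with sigmoid-calibrated probabilities, or a
#' k-nearest-neighbor vote (k = 5 by default), each trained directly on
#' the (possibly imbalanced) training split.
#'
#' @param data a two-class \linkS4class{LabeledDataset}.
#' @param family "rf", "svm" or "knn".
#' @param seed integer seed.
#' @param knn_k neighbor count for the KNN baseline.
#' @return A fitted baseline model with a \code{\link{predictProba}}
#'   method.
#' @export
fitBaseline <- function(data, family = c("rf", "svm", "knn"), seed = 1L,
                        knn_k = 5L) {
    family <- match.arg(family)
    stopIfSingleClass(data, "baseline training")
    stopIfMissingValues(data, "baseline training")
    inner <- switch(family,
        rf = fitMember(BaseLearnerSpec("random_forest"), data,
                       member_seed = as.integer(seed)),
        svm = fitMember(BaseLearnerSpec("svm"), data,
                        member_seed = as.integer(seed)),
        knn = structure(list(train = data@features,
                             labels = data@labels,
                             k = as.integer(knn_k),
                             seed = as.integer(seed)),
                        class = "spiderKnnMember"))
    structure(list(inner = inner, family = family,
                   feature_names = featNames(data)),
              class = "BaselineModel")
}

knnProba <- function(member, features) {
    pred <- withSeed(member$seed,
        class::knn(member$train, features,
                   factor(member$labels, levels = c(0L, 1L)),
                   k = member$k, prob = TRUE))
    win <- attr(pred, "prob")
    p1 <- ifelse(pred == "1", win, 1 - win)
    cbind("0" = 1 - p1, "1" = p1)
}

setOldClass("BaselineModel")

#' @describeIn predictProba probabilities from a plain baseline learner.
#' @export
setMethod("predictProba", "BaselineModel", function(object, features) {
    features <- checkFeatureWidth(object$feature_names, features)
    if (object$family == "knn") knnProba(object$inner, features)
    else memberProba(object$inner, features)
})

# ---- orchestration ------------------------------------------------------

prepSplit <- function(data, test_fraction, seed) {
    sp <- stratifiedSplit(imputeClassMean(data), test_fraction, seed)
    pars <- minmaxParams(sp@train)
    new("SplitResult", train = applyMinmax(sp@train, pars),
        test = applyMinmax(sp@test, pars), seed = sp@seed)
}

fitMethod <- function(method, train, rounds, k, seed,
                      resample_baselines = FALSE) {
    if (method == "proposed")
        return(fitEnsemble(train, rounds = rounds, resample_first = TRUE,
                           k = k, seed = seed))
    if (resample_baselines)
        train <- spiderResample(train, k = k, seed = seed)@dataset
    fitBaseline(train, family = method, seed = seed)
}

reportRow <- function(rep) {
    data.frame(accuracy = rep@accuracy, mcc = rep@mcc, rmse = rep@rmse,
               f1 = rep@f_score, auc = rep@auc)
}

#' Benchmark the proposed method against plain baselines
#'
#' For each dataset and method: impute (class means, train only), min-max
#' normalize with training ranges, stratified 80/20 split, train (the
#' proposed method applies the selective over-sampler and boosted voting
#' ensemble; baselines are trained plainly on the unbalanced split), and
#' evaluate.  A failing combination is recorded as a row-level error, not a
#' crash.
#'
#' @param datasets named list of \linkS4class{LabeledDataset} or file paths
#'   (\code{.dat} files read as KEEL, anything else as expression CSV).
#' @param methods subset of c("proposed", "rf", "svm", "knn").
#' @param test_fraction test fraction of the stratified split.
#' @param k resampler neighbor count; \code{rounds} boosting rounds.
#' @param rounds boosting rounds for the proposed ensemble.
#' @param seed integer seed; the whole table is deterministic given it.
#' @param resample_baselines also resample before the baselines (ablation).
#' @return data.frame with one row per dataset x method (metrics, or an
#'   error message in the \code{error} column).
#' @export
runBenchmark <- function(datasets, methods = c("proposed", "rf", "svm", "knn"),
                         test_fraction = 0.2, k = 3L, rounds = 10L,
                         seed = 1L, resample_baselines = FALSE) {
    stopifnot(length(datasets) >= 1, length(methods) >= 1)
    methods <- match.arg(methods, several.ok = TRUE)
    if (is.null(names(datasets)))
        names(datasets) <- paste0("dataset", seq_along(datasets))
    rows <- list()
    for (dname in names(datasets)) {
        d <- datasets[[dname]]
        if (is.character(d))
            d <- if (grepl("\\.dat$", d)) readKeel(d) else readExpressionCsv(d)
        sp <- prepSplit(d, test_fraction, seed)
        for (method in methods) {
            res <- tryCatch({
                model <- fitMethod(method, sp@train, rounds, k, seed,
                                   resample_baselines)
                cbind(data.frame(dataset = dname, method = method,
                                 stringsAsFactors = FALSE),
                      reportRow(evaluateModel(model, sp@test)),
                      data.frame(error = NA_character_))
            }, error = function(e) {
                data.frame(dataset = dname, method = method,
                           accuracy = NA_real_, mcc = NA_real_,
                           rmse = NA_real_, f1 = NA_real_, auc = NA_real_,
                           error = conditionMessage(e),
                           stringsAsFactors = FALSE)
            })
            rows[[length(rows) + 1L]] <- res
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Compare feature-selection strategies on one dataset
#'
#' For each feature set in \code{feature_sets}: ranks features on the
#' training split only (leakage guard), applies the cut-off, trains each
#' method on the restricted training split, and evaluates on the
#' restricted test split.  The "all" set skips ranking; the "degs" set
#' requires three-contrast stage data and uses the union of the up- and
#' down-regulated all-three intersections (restricted to the dataset's
#' features).
#'
#' @param data a \linkS4class{LabeledDataset}.
#' @param feature_sets subset of c("all", "chi2", "rfe", "boostfs", "degs").
#' @param n_keep cut-off applied to each ranking.
#' @param methods subset of c("proposed", "rf", "svm", "knn").
#' @param stage_data output of \code{\link{makeStageData}} (or a named list
#'   of three contrasts) for the "degs" set.
#' @param alpha DEG significance threshold.
#' @param test_fraction,k,rounds,seed as in \code{\link{runBenchmark}}.
#' @return data.frame with one row per feature set x method.
#' @export
runFeatureComparison <- function(data,
                                 feature_sets = c("all", "chi2", "rfe",
                                                  "boostfs", "degs"),
                                 n_keep = 100L,
                                 methods = c("proposed", "rf", "svm", "knn"),
                                 stage_data = NULL, alpha = 0.005,
                                 test_fraction = 0.2, k = 3L, rounds = 10L,
                                 seed = 1L) {
    feature_sets <- match.arg(feature_sets, several.ok = TRUE)
    methods <- match.arg(methods, several.ok = TRUE)
    sp <- prepSplit(data, test_fraction, seed)
    rows <- list()
    for (fs in feature_sets) {
        res <- tryCatch({
            keep_cols <- selectFeatureSet(fs, sp@train, n_keep, stage_data,
                                          alpha, seed)
            tr <- sp@train[, keep_cols]; te <- sp@test[, keep_cols]
            lapply(methods, function(method) {
                model <- fitMethod(method, tr, rounds, k, seed)
                cbind(data.frame(feature_set = fs, method = method,
                                 n_features = length(keep_cols),
                                 stringsAsFactors = FALSE),
                      reportRow(evaluateModel(model, te)),
                      data.frame(error = NA_character_))
            })
        }, error = function(e) {
            list(data.frame(feature_set = fs, method = NA_character_,
                            n_features = NA_integer_, accuracy = NA_real_,
                            mcc = NA_real_, rmse = NA_real_, f1 = NA_real_,
                            auc = NA_real_, error = conditionMessage(e),
                            stringsAsFactors = FALSE))
        })
        rows <- c(rows, res)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# feature-column selection per strategy, fitted on the training split only
selectFeatureSet <- function(fs, train, n_keep, stage_data, alpha, seed) {
    n_keep <- min(as.integer(n_keep), nFeatures(train))
    if (fs == "all") return(seq_len(nFeatures(train)))
    if (fs == "degs") {
        if (is.null(stage_data))
            stop("the degs feature set requires stage data", call. = FALSE)
        stages <- if (!is.null(stage_data$stages)) stage_data$stages
                  else stage_data
        deg <- selectDegs(stages, alpha = alpha)
        genes <- union(deg@intersection_up, deg@intersection_down)
        cols <- which(featNames(train) %in% genes)
        if (!length(cols))
            stop("no DEG-selected genes present in the dataset",
                 call. = FALSE)
        return(cols)
    }
    ranking <- switch(fs,
        chi2 = chi2Rank(train),
        rfe = rfeSvcRank(train, step = max(1L, nFeatures(train) %/% 10L)),
        boostfs = boostfsRank(train, seed = seed))
    sort(ranking@order[seq_len(n_keep)])
}
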