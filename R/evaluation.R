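#' Confusion counts from truth and prediction vectors
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(truth, pred) {
    stopifnot(length(truth) == length(pred))
    ConfusionCounts(tp = sum(truth == 1 & pred == 1),
                    tn = sum(truth == 0 & pred == 0),
                    fp = sum(truth == 0 & pred == 1),
                    fn = sum(truth == 1 & pred == 0))
}

#' Classification accuracy
#'
#' (TP + TN) / (TP + FN + TN + FP).
#'
#' @param c a \linkS4class{ConfusionCounts} with positive total.
#' @return accuracy in [0, 1].
#' @export
accuracyScore <- function(c) {
    tot <- c@tp + c@tn + c@fp + c@fn
    if (tot == 0) stop("empty confusion counts", call. = FALSE)
    (c@tp + c@tn) / tot
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)); returns 0 when any
#' denominator factor is zero (the conventional degenerate-classifier
#' value).  1 corresponds to an error-free classifier, -1 to a fully
#' inverted one.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @return MCC in [-1, 1].
#' @export
mccScore <- function(c) {
    tp <- as.double(c@tp); tn <- as.double(c@tn)
    fp <- as.double(c@fp); fn <- as.double(c@fn)
    den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / sqrt(den)
}

#' Root-mean-squared error
#'
#' sqrt(mean((targets - predictions)^2)).
#'
#' @param targets,predictions numeric vectors of equal positive length.
#' @return nonnegative RMSE.
#' @export
rmseScore <- function(targets, predictions) {
    if (length(targets) == 0 || length(targets) != length(predictions))
        stop("targets and predictions must have equal nonzero length",
             call. = FALSE)
    sqrt(mean((targets - predictions)^2))
}

#' F-score (F1)
#'
#' Harmonic mean of precision TP/(TP+FP) and recall TP/(TP+FN); 0 when
#' TP = 0.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @return F1 in [0, 1].
#' @export
fScore <- function(c) {
    if (c@tp == 0) return(0)
    prec <- c@tp / (c@tp + c@fp)
    rec <- c@tp / (c@tp + c@fn)
    2 * prec * rec / (prec + rec)
}

#' ROC curve and trapezoidal AUC
#'
#' Thresholds at every distinct score (ties share a threshold); the curve
#' runs from (0,0) to (1,1) in (false-positive-rate, true-positive-rate)
#' coordinates and the AUC is its trapezoidal area, which equals the
#' Mann-Whitney pair-counting statistic.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores numeric scores, higher = more positive.
#' @return list with \code{auc} and \code{roc_points} (data.frame fpr/tpr).
#' @export
rocAuc <- function(labels, scores) {
    stopifnot(length(labels) == length(scores))
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0)
        stop("ROC requires both classes in the labels", call. = FALSE)
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]; sc <- scores[ord]
    # cumulative counts at each distinct-threshold boundary
    last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
    tp <- cumsum(lab == 1)[last_of_tie]
    fp <- cumsum(lab == 0)[last_of_tie]
    tpr <- c(0, tp / n1, 1)
    fpr <- c(0, fp / n0, 1)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(auc = auc,
         roc_points = unique(data.frame(fpr = fpr, tpr = tpr)))
}

#' Evaluate a fitted model on a test set
#'
#' Predicts positive-class probabilities via \code{\link{predictProba}},
#' derives hard labels (ensembles use their tie rule via
#' \code{\link{predictEnsemble}}; other models threshold at 0.5), and
#' assembles the full metric suite: confusion counts, accuracy, MCC,
#' RMSE, F-score and trapezoidal ROC/AUC on the positive-class
#' probability.
#'
#' @param model a \linkS4class{VotingEnsemble},
#'   \linkS4class{BoostedCommittee} or baseline model with a
#'   \code{predictProba} method.
#' @param test a \linkS4class{LabeledDataset} with both classes present.
#' @param rmse_on one of "labels" (default: RMSE on hard 0/1 predictions,
#'   so RMSE = sqrt(1 - accuracy)) or "proba" (RMSE on the positive-class
#'   probability).
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateModel <- function(model, test, rmse_on = c("labels", "proba")) {
    rmse_on <- match.arg(rmse_on)
    stopIfSingleClass(test, "evaluation")
    if (is(model, "VotingEnsemble")) {
        pr <- predictEnsemble(model, test@features)
        proba <- pr$proba; labels <- pr$labels
    } else {
        proba <- predictProba(model, test@features)
        labels <- as.integer(proba[, "1"] >= 0.5)
    }
    cc <- confusionCounts(test@labels, labels)
    roc <- rocAuc(test@labels, proba[, "1"])
    pred_for_rmse <- if (rmse_on == "labels") labels else proba[, "1"]
    new("EvaluationReport", counts = cc,
        accuracy = accuracyScore(cc), mcc = mccScore(cc),
        rmse = rmseScore(test@labels, pred_for_rmse),
        f_score = fScore(cc), auc = roc$auc, roc_points = roc$roc_points)
}

#' Serialize an EvaluationReport to the report JSON schema
#'
#' Schema: \code{{counts:{tp,tn,fp,fn}, accuracy, mcc, rmse, f1, auc,
#' roc:[[fpr,tpr],...]}}.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return \code{path} (invisibly) or the JSON string.
#' @export
reportToJson <- function(report, path = NULL) {
    x <- list(counts = list(tp = report@counts@tp, tn = report@counts@tn,
                            fp = report@counts@fp, fn = report@counts@fn),
              accuracy = report@accuracy, mcc = report@mcc,
              rmse = report@rmse, f1 = report@f_score, auc = report@auc,
              roc = unname(as.matrix(report@roc_points)))
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
    if (is.null(path)) return(as.character(json))
    writeLines(as.character(json), path)
    invisible(path)
}
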