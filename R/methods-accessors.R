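#' @rdname accessors
setMethod("featureMatrix", "LabeledDataset", function(x) x@features)

#' @rdname accessors
setMethod("classLabels", "LabeledDataset", function(x) x@labels)

#' @rdname accessors
setMethod("sampleIds", "LabeledDataset", function(x) rownames(x@features))

#' @rdname accessors
setMethod("featNames", "LabeledDataset", function(x) colnames(x@features))

#' @rdname accessors
setMethod("nSamples", "LabeledDataset", function(x) nrow(x@features))

#' @rdname accessors
setMethod("nFeatures", "LabeledDataset", function(x) ncol(x@features))

#' @rdname accessors
setMethod("imbalanceRatio", "LabeledDataset", function(x) {
    n1 <- sum(x@labels == 1L)
    n0 <- sum(x@labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("imbalance ratio undefined for single-class data")
    max(n0, n1) / min(n0, n1)
})

#' @rdname accessors
setMethod("featureMatrix", "ResampleResult", function(x) x@dataset@features)
#' @rdname accessors
setMethod("classLabels", "ResampleResult", function(x) x@dataset@labels)
#' @rdname accessors
setMethod("imbalanceRatio", "ResampleResult",
          function(x) imbalanceRatio(x@dataset))

#' Subset a LabeledDataset by samples and/or features
#'
#' @param x a \linkS4class{LabeledDataset}.
#' @param i sample index (integer, logical or sample-id character).
#' @param j feature index (integer, logical or feature-name character).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@features))
    if (missing(j)) j <- seq_len(ncol(x@features))
    new("LabeledDataset", features = x@features[i, j, drop = FALSE],
        labels = x@labels[i])
})

setMethod("show", "LabeledDataset", function(object) {
    n1 <- sum(object@labels == 1L)
    n0 <- sum(object@labels == 0L)
    cat(sprintf("LabeledDataset: %d samples x %d features\n",
                nSamples(object), nFeatures(object)))
    cat(sprintf("  class 0 (negative/majority): %d\n", n0))
    cat(sprintf("  class 1 (positive/minority): %d\n", n1))
    if (n0 > 0 && n1 > 0)
        cat(sprintf("  imbalance ratio: %.2f\n", imbalanceRatio(object)))
    nmiss <- sum(is.na(object@features))
    if (nmiss > 0) cat(sprintf("  missing cells: %d\n", nmiss))
})

setMethod("show", "SplitResult", function(object) {
    cat(sprintf("SplitResult (seed %d): train %d / test %d samples\n",
                object@seed, nSamples(object@train), nSamples(object@test)))
})

setMethod("show", "ResampleResult", function(object) {
    nsyn <- sum(object@provenance == "synthetic")
    cat(sprintf("ResampleResult (seed %d): %d originals + %d synthetic\n",
                object@seed, sum(object@provenance == "original"), nsyn))
    cat(sprintf("  output imbalance ratio: %.2f\n",
                imbalanceRatio(object@dataset)))
    tab <- table(object@flags$strength, useNA = "no")
    if (length(tab))
        cat("  minority strength: ",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "FeatureRanking", function(object) {
    top <- head(names(object@scores)[object@order], 5)
    cat(sprintf("FeatureRanking (%s): %d features\n",
                object@method, length(object@scores)))
    cat("  top: ", paste(top, collapse = ", "), "\n")
})

setMethod("show", "DEGResult", function(object) {
    cat(sprintf("DEGResult (alpha = %g): %d contrasts\n",
                object@alpha, length(object@per_contrast)))
    for (nm in names(object@per_contrast)) {
        pc <- object@per_contrast[[nm]]
        cat(sprintf("  %s: %d DE (%d up, %d down)\n", nm, sum(pc$de),
                    sum(pc$de & pc$direction == "up"),
                    sum(pc$de & pc$direction == "down")))
    }
    cat(sprintf("  all-three intersection: %d up, %d down\n",
                length(object@intersection_up),
                length(object@intersection_down)))
})

setMethod("show", "BoostedCommittee", function(object) {
    cat(sprintf("BoostedCommittee (%s): %d member(s) of %d round(s)\n",
                object@spec@family, length(object@members), object@rounds))
    cat("  alphas:", paste(sprintf("%.3f", object@member_weights),
                           collapse = ", "), "\n")
})

setMethod("show", "VotingEnsemble", function(object) {
    fams <- vapply(object@arms, function(a) a@spec@family, character(1))
    cat(sprintf("VotingEnsemble: %d arms (%s), tie rule = %s\n",
                length(object@arms), paste(fams, collapse = " + "),
                object@tie_rule))
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d\n",
                object@tp, object@tn, object@fp, object@fn))
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    show(object@counts)
    cat(sprintf("  accuracy=%.4f mcc=%.4f rmse=%.4f f1=%.4f auc=%.4f\n",
                object@accuracy, object@mcc, object@rmse, object@f_score,
                object@auc))
})
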