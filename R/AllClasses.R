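#' @import methods
NULL

#' LabeledDataset: a labeled expression-style feature table
#'
#' The universal currency of the package: a numeric samples-by-features
#' matrix together with a binary class label per sample.  Label 1 is always
#' the positive class (patients / the minority class); label 0 the negative
#' class (controls / the majority).  Missing values are carried as \code{NA}
#' in the matrix and resolved by \code{\link{imputeClassMean}}.
#'
#' @slot features numeric matrix, samples in rows, features in columns;
#'   rownames are sample ids, colnames feature names, both unique.
#' @slot labels integer vector of 0/1, one per sample.
#'
#' @seealso \code{\link{readExpressionCsv}}, \code{\link{readKeel}},
#'   \code{\link{makeImbalanced}}
#' @export
setClass("LabeledDataset",
         representation(features = "matrix", labels = "integer"))

setValidity("LabeledDataset", function(object) {
    f <- object@features
    msgs <- character()
    if (!is.numeric(f)) msgs <- c(msgs, "features must be a numeric matrix")
    if (nrow(f) != length(object@labels))
        msgs <- c(msgs, "row count of features must equal length of labels")
    if (!all(object@labels %in% c(0L, 1L)))
        msgs <- c(msgs, "labels must be 0 or 1")
    if (is.null(rownames(f)) || anyDuplicated(rownames(f)))
        msgs <- c(msgs, "sample ids (rownames) must be present and unique")
    if (is.null(colnames(f)) || anyDuplicated(colnames(f)))
        msgs <- c(msgs, "feature names (colnames) must be present and unique")
    if (length(msgs)) msgs else TRUE
})

#' Construct a LabeledDataset
#'
#' @param features numeric matrix (samples x features).
#' @param labels vector coercible to 0/1 integers, one per row of
#'   \code{features}.
#' @param feature_names,sample_ids optional character vectors overriding the
#'   dimnames of \code{features}; defaults are generated when absent.
#' @return A \linkS4class{LabeledDataset}.
#' @examples
#' d <- LabeledDataset(matrix(rnorm(12), 4, 3), c(0, 0, 1, 1))
#' nSamples(d)
#' @export
LabeledDataset <- function(features, labels,
                           feature_names = NULL, sample_ids = NULL) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (!is.null(feature_names)) colnames(features) <- feature_names
    if (!is.null(sample_ids)) rownames(features) <- sample_ids
    if (is.null(colnames(features)))
        colnames(features) <- paste0("f", seq_len(ncol(features)))
    if (is.null(rownames(features)))
        rownames(features) <- paste0("s", seq_len(nrow(features)))
    new("LabeledDataset", features = features,
        labels = as.integer(labels))
}

#' SplitResult: a stratified train/test partition
#'
#' @slot train,test \linkS4class{LabeledDataset} partitions with disjoint
#'   sample ids whose union is the input's.
#' @slot seed integer seed that produced the partition.
#' @export
setClass("SplitResult",
         representation(train = "LabeledDataset", test = "LabeledDataset",
                        seed = "integer"))

#' ResampleResult: output of the selective over-sampler
#'
#' Holds the augmented dataset (originals plus interpolated minority
#' samples), the per-original-sample kNN flags, per-sample provenance, and
#' the synthesis record linking each synthetic sample to its parent and the
#' neighbor it was interpolated towards.
#'
#' @slot dataset \linkS4class{LabeledDataset} of originals + synthetics.
#' @slot flags data.frame over original samples: \code{sample_id},
#'   \code{class}, \code{knn_flag} (safe/noisy), \code{strength}
#'   (weak/strong/excluded for minority, NA for majority).
#' @slot provenance character, "original"/"synthetic", one per row of
#'   \code{dataset}.
#' @slot synthesis data.frame over synthetic samples: \code{sample_id},
#'   \code{parent_id}, \code{neighbor_id}, \code{u} (interpolation draw).
#' @slot seed integer.
#' @export
setClass("ResampleResult",
         representation(dataset = "LabeledDataset", flags = "data.frame",
                        provenance = "character", synthesis = "data.frame",
                        seed = "integer"))

setValidity("ResampleResult", function(object) {
    msgs <- character()
    if (length(object@provenance) != nSamples(object@dataset))
        msgs <- c(msgs, "provenance must cover every sample")
    if (!all(object@provenance %in% c("original", "synthetic")))
        msgs <- c(msgs, "provenance values must be original/synthetic")
    syn <- object@provenance == "synthetic"
    if (any(object@dataset@labels[syn] != 1L))
        msgs <- c(msgs, "synthetic samples must carry the minority label (1)")
    if (length(msgs)) msgs else TRUE
})

#' FeatureRanking: ordered per-feature relevance scores
#'
#' @slot method one of "chi2", "rfe_svc", "boostfs", "degs".
#' @slot scores named numeric, one score per feature (higher = more
#'   relevant).
#' @slot order integer permutation of feature indices sorting scores
#'   descending, ties broken by ascending feature index.
#' @export
setClass("FeatureRanking",
         representation(method = "character", scores = "numeric",
                        order = "integer"))

setValidity("FeatureRanking", function(object) {
    msgs <- character()
    if (!object@method %in% c("chi2", "rfe_svc", "boostfs", "degs"))
        msgs <- c(msgs, "unknown ranking method")
    if (length(object@order) != length(object@scores) ||
        !setequal(object@order, seq_along(object@scores)))
        msgs <- c(msgs, "order must be a permutation of feature indices")
    s <- object@scores[object@order]
    if (length(s) > 1 && any(diff(s) > 1e-12))
        msgs <- c(msgs, "order must sort scores in descending order")
    if (length(msgs)) msgs else TRUE
})

#' DEGResult: three-contrast differential-expression selection
#'
#' @slot per_contrast named list of three data.frames (gene, effect, p,
#'   adj_p, direction, de), one per contrast.
#' @slot intersection_up,intersection_down character vectors of genes
#'   up-/down-regulated (adjusted p below alpha, consistent direction) in
#'   all three contrasts; the two sets are disjoint.
#' @slot alpha numeric significance threshold on BH-adjusted p.
#' @export
setClass("DEGResult",
         representation(per_contrast = "list",
                        intersection_up = "character",
                        intersection_down = "character",
                        alpha = "numeric"))

setValidity("DEGResult", function(object) {
    if (length(intersect(object@intersection_up, object@intersection_down)))
        "up and down intersections must be disjoint" else TRUE
})

#' BaseLearnerSpec: configuration of one committee's base-learner family
#'
#' Defaults follow the ensemble's stated configuration: a 100-tree forest
#' with 10 randomly selected attributes per tree, and an RBF-kernel SVM with
#' C = 1 and a 1/(n_features * var) gamma.
#'
#' @slot family "random_forest", "svm" or "gbt".
#' @slot rf_trees,rf_features_per_tree forest size and per-tree feature
#'   draw (clipped to n_features at fit time).
#' @slot svm_kernel "rbf" or "linear"; \code{svm_C} the soft-margin cost;
#'   \code{svm_gamma} kernel width, \code{NA} = scale-style
#'   1/(n_features*var).
#' @slot seed integer.
#' @export
setClass("BaseLearnerSpec",
         representation(family = "character", rf_trees = "integer",
                        rf_features_per_tree = "integer",
                        svm_kernel = "character", svm_C = "numeric",
                        svm_gamma = "numeric", seed = "integer"))

#' @rdname BaseLearnerSpec-class
#' @param family,rf_trees,rf_features_per_tree,svm_kernel,svm_C,svm_gamma,seed
#'   see the class slots.
#' @export
BaseLearnerSpec <- function(family = c("random_forest", "svm", "gbt"),
                            rf_trees = 100L, rf_features_per_tree = 10L,
                            svm_kernel = c("rbf", "linear"),
                            svm_C = 1, svm_gamma = NA_real_, seed = 1L) {
    new("BaseLearnerSpec", family = match.arg(family),
        rf_trees = as.integer(rf_trees),
        rf_features_per_tree = as.integer(rf_features_per_tree),
        svm_kernel = match.arg(svm_kernel), svm_C = svm_C,
        svm_gamma = svm_gamma, seed = as.integer(seed))
}

#' BoostedCommittee: an AdaBoost-style committee of one base-learner family
#'
#' @slot members list of fitted member models (internal wrapper objects).
#' @slot member_weights numeric alpha per member, finite and >= 0.
#' @slot spec the \linkS4class{BaseLearnerSpec} used.
#' @slot rounds requested boosting rounds; \code{length(members) <= rounds}.
#' @slot feature_names training feature names, enforced at prediction.
#' @export
setClass("BoostedCommittee",
         representation(members = "list", member_weights = "numeric",
                        spec = "BaseLearnerSpec", rounds = "integer",
                        feature_names = "character"))

setValidity("BoostedCommittee", function(object) {
    msgs <- character()
    if (length(object@members) != length(object@member_weights))
        msgs <- c(msgs, "one weight per member required")
    if (length(object@members) < 1L || length(object@members) > object@rounds)
        msgs <- c(msgs, "committee must have between 1 and rounds members")
    if (!all(is.finite(object@member_weights)) ||
        any(object@member_weights < 0))
        msgs <- c(msgs, "member weights must be finite and nonnegative")
    if (length(msgs)) msgs else TRUE
})

#' VotingEnsemble: probability-voting combination of boosted committees
#'
#' Two heterogeneous arms (random-forest family and SVM family; optionally a
#' third gradient-boosted-tree arm), each a \linkS4class{BoostedCommittee},
#' combined by averaging class probabilities.  An exact probability tie is
#' resolved by \code{tie_rule} (default: minority/positive class).
#'
#' @slot arms list of \linkS4class{BoostedCommittee}, distinct families.
#' @slot tie_rule "minority" or "majority".
#' @slot feature_names training feature names.
#' @export
setClass("VotingEnsemble",
         representation(arms = "list", tie_rule = "character",
                        feature_names = "character"))

setValidity("VotingEnsemble", function(object) {
    fams <- vapply(object@arms, function(a) a@spec@family, character(1))
    msgs <- character()
    if (anyDuplicated(fams)) msgs <- c(msgs, "arms must have distinct families")
    if (!object@tie_rule %in% c("minority", "majority"))
        msgs <- c(msgs, "tie_rule must be minority or majority")
    if (length(msgs)) msgs else TRUE
})

#' ConfusionCounts: the 2x2 confusion matrix of a binary classifier
#'
#' @slot tp,tn,fp,fn nonnegative integer counts; their sum is >= 1.
#' @export
setClass("ConfusionCounts",
         representation(tp = "integer", tn = "integer",
                        fp = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0)) return("counts must be nonnegative")
    if (sum(v) < 1) return("at least one count must be positive")
    TRUE
})

#' @rdname ConfusionCounts-class
#' @param tp,tn,fp,fn nonnegative integers.
#' @export
ConfusionCounts <- function(tp, tn, fp, fn) {
    new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
        fp = as.integer(fp), fn = as.integer(fn))
}

#' EvaluationReport: full metric suite for one classifier on one test set
#'
#' @slot counts \linkS4class{ConfusionCounts} at the 0.5 probability cut.
#' @slot accuracy,mcc,rmse,f_score,auc scalar metrics; accuracy, F-score and
#'   AUC in [0,1], MCC in [-1,1], RMSE >= 0.
#' @slot roc_points data.frame (fpr, tpr) from (0,0) to (1,1), both
#'   coordinates nondecreasing.
#' @export
setClass("EvaluationReport",
         representation(counts = "ConfusionCounts", accuracy = "numeric",
                        mcc = "numeric", rmse = "numeric",
                        f_score = "numeric", auc = "numeric",
                        roc_points = "data.frame"))

setValidity("EvaluationReport", function(object) {
    msgs <- character()
    inunit <- function(x) is.finite(x) && x >= 0 && x <= 1
    if (!inunit(object@accuracy)) msgs <- c(msgs, "accuracy outside [0,1]")
    if (!inunit(object@f_score)) msgs <- c(msgs, "f_score outside [0,1]")
    if (!inunit(object@auc)) msgs <- c(msgs, "auc outside [0,1]")
    if (!is.finite(object@mcc) || abs(object@mcc) > 1)
        msgs <- c(msgs, "mcc outside [-1,1]")
    if (object@rmse < 0) msgs <- c(msgs, "rmse negative")
    rp <- object@roc_points
    if (nrow(rp) < 2 || any(rp[1, ] != c(0, 0)) || any(rp[nrow(rp), ] != c(1, 1)))
        msgs <- c(msgs, "roc_points must run from (0,0) to (1,1)")
    if (is.unsorted(rp$fpr) || is.unsorted(rp$tpr))
        msgs <- c(msgs, "roc coordinates must be nondecreasing")
    if (length(msgs)) msgs else TRUE
})
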