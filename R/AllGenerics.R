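#' Accessors for LabeledDataset and friends
#'
#' \code{featureMatrix} returns the samples-by-features numeric matrix;
#' \code{classLabels} the 0/1 integer labels; \code{sampleIds} and
#' \code{featNames} the respective identifier vectors; \code{nSamples} and
#' \code{nFeatures} the dimensions; \code{imbalanceRatio} the
#' majority-over-minority count ratio (1 = balanced).
#'
#' @param x a \linkS4class{LabeledDataset} (or, where documented, a
#'   \linkS4class{ResampleResult}).
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("featNames", function(x) standardGeneric("featNames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))
#' @rdname accessors
#' @export
setGeneric("imbalanceRatio", function(x) standardGeneric("imbalanceRatio"))

#' Positive-class probabilities from a fitted model
#'
#' Returns an n-by-2 matrix of class probabilities (columns "0" and "1",
#' rows summing to 1) for new samples.  Methods exist for
#' \linkS4class{BoostedCommittee}, \linkS4class{VotingEnsemble} and the
#' plain baseline learners used by the benchmark harness.
#'
#' @param object a fitted model.
#' @param features numeric matrix whose columns match the training features.
#' @return numeric matrix [n x 2] of probabilities.
#' @export
setGeneric("predictProba",
           function(object, features) standardGeneric("predictProba"))
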