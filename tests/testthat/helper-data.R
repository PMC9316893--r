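# Shared fixture builders and independent oracles.

toyDataset <- function(coords, labels) {
    LabeledDataset(as.matrix(coords), labels)
}

# Independent kNN safe/noisy oracle: brute-force all pairwise distances
# with pairwiseDistance, sort each sample's neighbor list (ties by lower
# index), take the k nearest, majority-vote (tie -> safe).
bruteKnnOracle <- function(data, k) {
    mat <- featureMatrix(data)
    lab <- classLabels(data)
    n <- nrow(mat)
    vapply(seq_len(n), function(i) {
        others <- setdiff(seq_len(n), i)
        d <- vapply(others, function(j) pairwiseDistance(mat[i, ], mat[j, ]),
                    numeric(1))
        nn <- others[order(d, others)][seq_len(k)]
        own <- sum(lab[nn] == lab[i])
        if (own >= k - own) "safe" else "noisy"
    }, character(1))
}

# Independent AUC oracle: exhaustive Mann-Whitney pair counting, ties
# scored 1/2.
bruteAucOracle <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# Stub SVM-family member whose decision value is a fixed function of the
# features; used to exercise committee/ensemble arithmetic with known
# probabilities.
stubMember <- function(decision_fun, coefs = c(0, 1)) {
    structure(list(model = NULL, coefs = coefs,
                   decisionFor = function(m, x) decision_fun(x)),
              class = "spiderSvmMember")
}

stubCommittee <- function(members, weights, feature_names) {
    new("BoostedCommittee", members = members,
        member_weights = weights,
        spec = BaseLearnerSpec("svm"), rounds = length(members),
        feature_names = feature_names)
}

stubEnsemble <- function(arms, tie_rule, feature_names) {
    new("VotingEnsemble", arms = arms, tie_rule = tie_rule,
        feature_names = feature_names)
}

# Gaussian two-cluster toy set that a linear separator handles perfectly.
separableDataset <- function(n_per_class = 10, gap = 6, seed = 1) {
    set.seed(seed)
    mat <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
                 matrix(rnorm(2 * n_per_class, mean = gap), ncol = 2))
    LabeledDataset(mat, rep(c(0L, 1L), each = n_per_class))
}
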