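test_that("balanced subsets honor sizes, weights and degenerate draws", {
    d <- separableDataset(25, seed = 2)
    w <- rep(1, nSamples(d))
    sub <- drawBalancedSubset(d, w, 5, rng_seed = 1)
    expect_identical(as.vector(table(classLabels(sub))), c(5L, 5L))
    # all weight on one sample per class -> that sample fills every slot
    # needing replacement
    w2 <- rep(0, nSamples(d)); w2[c(1, 26)] <- 1
    sub2 <- drawBalancedSubset(d, w2, 4, rng_seed = 3)
    expect_true(all(featureMatrix(sub2)[classLabels(sub2) == 0L, 1] ==
                    featureMatrix(d)[1, 1]))
    expect_error(drawBalancedSubset(d, rep(0, nSamples(d)), 3, 1),
                 "zero total weight")
})

test_that("inclusion frequency tracks the weights over repeated draws", {
    d <- separableDataset(10, seed = 5)
    w <- c(4, 2, 2, 1, 1, rep(0, 5),   # class 0 weights
           rep(1, 10))                  # class 1 uniform
    hits <- numeric(nSamples(d))
    ndraw <- 2000
    for (i in seq_len(ndraw)) {
        sub <- drawBalancedSubset(d, w, 1, rng_seed = i)
        id0 <- sampleIds(sub)[classLabels(sub) == 0L]
        hits[match(id0, sampleIds(d))] <- hits[match(id0, sampleIds(d))] + 1
    }
    freq <- hits[1:5] / ndraw
    expect_true(all(abs(freq - c(4, 2, 2, 1, 1) / 10) <= 0.03))
})

test_that("single-round boosting yields one member with error-driven alpha", {
    d <- separableDataset(8, seed = 3)
    cmt <- boostFit(BaseLearnerSpec("random_forest"), d, rounds = 1,
                    seed = 4)
    expect_length(cmt@members, 1)
    expect_true(is.finite(cmt@member_weights) && cmt@member_weights >= 0)
})

test_that("perfectly separable data terminates boosting after one member", {
    d <- separableDataset(10, gap = 10, seed = 6)
    cmt <- boostFit(BaseLearnerSpec("random_forest"), d, rounds = 10,
                    seed = 2)
    expect_length(cmt@members, 1)       # zero training error ends the loop
    expect_true(is.finite(cmt@member_weights))
})

test_that("committee probabilities are alpha-weighted member averages", {
    feats <- matrix(c(0.2, 0.8), 2, 2,
                    dimnames = list(NULL, c("a", "b")))
    m1 <- stubMember(function(x) rep(log(0.8 / 0.2), nrow(x)))  # p1 = 0.8
    m2 <- stubMember(function(x) rep(log(0.6 / 0.4), nrow(x)))  # p1 = 0.6
    single <- stubCommittee(list(m1), 1.0, c("a", "b"))
    expect_equal(unname(predictProba(single, feats)[1, ]), c(0.2, 0.8))
    pair <- stubCommittee(list(m1, m2), c(1, 1), c("a", "b"))
    expect_equal(unname(predictProba(pair, feats)[1, ]), c(0.3, 0.7))
    # all-zero alphas fall back to uniform weighting
    zero <- stubCommittee(list(m1, m2), c(0, 0), c("a", "b"))
    expect_equal(predictProba(zero, feats), predictProba(pair, feats))
    expect_equal(unname(rowSums(predictProba(pair, feats))), c(1, 1))
})

test_that("a single-round uniform-weight RF arm equals a direct forest", {
    # class-0 rows first so the exhaustive balanced draw is the identity
    d <- separableDataset(12, gap = 3, seed = 9)
    cmt <- boostFit(BaseLearnerSpec("random_forest"), d, rounds = 1,
                    per_class_size = 12, seed = 31)
    direct <- spiderVote:::withSeed(spiderVote:::childSeed(31, 1),
        randomForest::randomForest(featureMatrix(d),
            factor(classLabels(d), levels = c(0L, 1L)),
            ntree = 100, mtry = 2))
    probe <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, featNames(d)))
    expect_equal(unname(predictProba(cmt, probe)[, "1"]),
                 unname(predict(direct, probe, type = "prob")[, "1"]))
})

test_that("ensemble fitting is deterministic and structured as specified", {
    d <- separableDataset(10, gap = 4, seed = 11)
    ens <- fitEnsemble(d, rounds = 1, resample_first = FALSE, seed = 5)
    expect_length(ens@arms, 2)
    fams <- vapply(ens@arms, function(a) a@spec@family, character(1))
    expect_setequal(fams, c("random_forest", "svm"))
    expect_true(all(lengths(lapply(ens@arms, slot, "members")) == 1))
    probe <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, featNames(d)))
    p1 <- predictEnsemble(ens, probe)
    ens2 <- fitEnsemble(d, rounds = 1, resample_first = FALSE, seed = 5)
    expect_identical(predictEnsemble(ens2, probe), p1)
    # optional third arm
    ens3 <- fitEnsemble(d, rounds = 1, resample_first = FALSE, seed = 5,
                        with_gbt_arm = TRUE)
    expect_length(ens3@arms, 3)
})

test_that("voting averages arms and resolves exact ties by the tie rule", {
    feats <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
    arm_a <- stubCommittee(list(stubMember(function(x)
        rep(log(0.1 / 0.9), nrow(x)))), 1, c("a", "b"))      # p1 = 0.1
    arm_b <- stubCommittee(list(stubMember(function(x)
        rep(log(0.3 / 0.7), nrow(x)))), 1, c("a", "b"))      # p1 = 0.3
    arm_b@spec <- BaseLearnerSpec("random_forest")           # distinct family
    ens <- stubEnsemble(list(arm_a, arm_b), "minority", c("a", "b"))
    pr <- predictEnsemble(ens, feats)
    expect_equal(unname(pr$proba[1, ]), c(0.8, 0.2))
    expect_identical(pr$labels, c(0L, 0L))
    # exact (0.5, 0.5) tie
    half <- stubCommittee(list(stubMember(function(x) rep(0, nrow(x)))),
                          1, c("a", "b"))
    tie_min <- stubEnsemble(list(half), "minority", c("a", "b"))
    tie_maj <- stubEnsemble(list(half), "majority", c("a", "b"))
    expect_identical(predictEnsemble(tie_min, feats)$labels, c(1L, 1L))
    expect_identical(predictEnsemble(tie_maj, feats)$labels, c(0L, 0L))
})

test_that("prediction rejects mismatched feature widths", {
    d <- separableDataset(8, seed = 13)
    ens <- fitEnsemble(d, rounds = 1, resample_first = FALSE, seed = 1)
    expect_error(predictEnsemble(ens, matrix(0, 3, 5)), "feature width")
})

test_that("boosting more rounds does not hurt accuracy on imbalanced data", {
    accs <- vapply(1:6, function(seed) {
        sim <- makeImbalanced(100, 20, n_features = 8, n_informative = 4,
                              effect = 0.8, seed = seed)
        sp <- stratifiedSplit(sim$dataset, 0.25, seed = seed)
        acc <- function(rounds) {
            cmt <- boostFit(BaseLearnerSpec("random_forest"), sp@train,
                            rounds = rounds, seed = seed)
            pred <- as.integer(
                predictProba(cmt, featureMatrix(sp@test))[, "1"] >= 0.5)
            mean(pred == classLabels(sp@test))
        }
        acc(5) - acc(1)
    }, numeric(1))
    expect_gte(mean(accs), 0)
})
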