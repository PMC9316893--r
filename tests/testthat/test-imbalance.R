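# Hand-traced 8-point layout used throughout: five majority samples (a
# tight cluster at the origin plus one interloper inside the minority
# cluster) and three minority samples (two clustered, one stranded in the
# majority cluster), k = 3.  The expected flags, strengths, amplification
# counts and synthesis plan below were derived by hand from the sorted
# neighbor lists.
tracePoints <- function() {
    toyDataset(rbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(0, 1),
                     s4 = c(1, 1), s5 = c(4, 4), s6 = c(5, 4),
                     s7 = c(5, 5), s8 = c(2, 2)),
               c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
}

test_that("pairwise Euclidean distance matches closed forms", {
    expect_equal(pairwiseDistance(c(0, 0), c(3, 4)), 5)
    expect_equal(pairwiseDistance(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(pairwiseDistance(c(1, 1, 1), c(0, 0, 0)), sqrt(3))
    expect_error(pairwiseDistance(1:2, 1:3), "equal length")
})

test_that("kNN flags follow forced neighborhoods", {
    fl <- knnFlag(tracePoints(), k = 3)
    expect_identical(fl$knn_flag,
                     c("safe", "safe", "safe", "safe", "noisy", "safe",
                       "safe", "noisy"))
    expect_identical(fl$sample_id, paste0("s", 1:8))
})

test_that("kNN flags equal the brute-force oracle on random layouts", {
    for (seed in 1:50) {
        set.seed(seed)
        d <- LabeledDataset(matrix(rnorm(40), 20, 2),
                            rbinom(20, 1, 0.4))
        if (min(table(classLabels(d))) < 3) next
        fl <- knnFlag(d, k = 3)
        expect_identical(fl$knn_flag, bruteKnnOracle(d, 3),
                         info = paste("seed", seed))
    }
})

test_that("kNN flagging validates k against the class sizes", {
    d <- tracePoints()
    expect_error(knnFlag(d, k = 8), "smaller than the number of samples")
    expect_error(knnFlag(d, k = 4), "at least k samples")
})

test_that("minority partition matches the hand trace", {
    d <- tracePoints()
    fl <- partitionMinority(d, knnFlag(d, 3), 3)
    expect_identical(fl$strength,
                     c(NA, NA, NA, NA, NA, "weak", "weak", "excluded"))
})

test_that("removing a noisy majority neighbor can flip weak to strong", {
    # p sits next to two majority points (m_star, m2) and two minority
    # ones; with m_star in the pool its 3-NN are {m_star, m2, q1} (2
    # majority -> weak), without it {m2, q1, q2} (1 majority -> strong).
    coords <- rbind(p = c(0, 0), m_star = c(1, 0), m2 = c(0, 1),
                    q1 = c(1.5, 0), q2 = c(0, -1.6),
                    m3 = c(20, 20), m4 = c(21, 20), m5 = c(20, 21),
                    m6 = c(21, 21), q3 = c(30, 30), q4 = c(31, 30),
                    q5 = c(30, 31))
    labels <- c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 1L)
    d <- toyDataset(coords, labels)
    all_safe <- data.frame(sample_id = sampleIds(d), class = labels,
                           knn_flag = "safe", stringsAsFactors = FALSE)
    with_noise <- all_safe
    with_noise$knn_flag[2] <- "noisy"  # m_star
    expect_identical(partitionMinority(d, all_safe, 3)$strength[1], "weak")
    expect_identical(partitionMinority(d, with_noise, 3)$strength[1],
                     "strong")
})

test_that("resampling the traced layout reproduces the manual trace", {
    d <- tracePoints()
    rs <- spiderResample(d, k = 3, seed = 11)
    # flags: s5 noisy majority, s8 excluded minority, s6/s7 weak (2
    # majority each among their pool 3-NN, so c = 2 apiece)
    expect_identical(rs@flags$knn_flag[c(5, 8)], c("noisy", "noisy"))
    expect_identical(rs@flags$strength[6:8], c("weak", "weak", "excluded"))
    # majority = 5, minority = 3: the plan s6,s6,s7,s7 stops after two
    # syntheses when the balance target is met
    expect_identical(nrow(rs@synthesis), 2L)
    expect_identical(rs@synthesis$parent_id, c("s6", "s6"))
    expect_true(all(rs@synthesis$neighbor_id %in% c("s7", "s4", "s2")))
    expect_equal(imbalanceRatio(rs), 1)
    # no originals lost, synthetics carry the minority label
    expect_identical(featureMatrix(rs)[1:8, ], featureMatrix(d))
    expect_identical(classLabels(rs), c(classLabels(d), 1L, 1L))
})

test_that("synthetic samples lie on the parent-neighbor segment", {
    sim <- makeImbalanced(30, 8, n_features = 4, effect = 1.5, seed = 3)
    rs <- spiderResample(sim$dataset, k = 3, seed = 21)
    mat <- featureMatrix(rs)
    for (r in seq_len(nrow(rs@synthesis))) {
        syn <- mat[rs@synthesis$sample_id[r], ]
        par <- mat[rs@synthesis$parent_id[r], ]
        nb <- mat[rs@synthesis$neighbor_id[r], ]
        expect_true(all(syn >= pmin(par, nb) - 1e-12 &
                        syn <= pmax(par, nb) + 1e-12))
    }
})

test_that("resampling invariants hold across random generator datasets", {
    for (seed in 1:40) {
        sim <- makeImbalanced(10 + (seed %% 4) * 7, 3 + seed %% 5,
                              n_features = 4, effect = 1.0,
                              seed = seed)
        d <- sim$dataset
        rs <- tryCatch(spiderResample(d, k = 3, seed = seed),
                       error = function(e) e)
        if (inherits(rs, "error")) {
            expect_match(conditionMessage(rs), "no seeds", info = seed)
            next
        }
        expect_lte(imbalanceRatio(rs), imbalanceRatio(d))
        expect_gte(imbalanceRatio(rs), 1)
        expect_gte(sum(classLabels(rs) == 1L), sum(classLabels(d) == 1L))
        orig <- rs@provenance == "original"
        expect_identical(featureMatrix(rs)[orig, , drop = FALSE],
                         featureMatrix(d))
    }
})

test_that("resampling is deterministic given (data, k, seed)", {
    d <- makeImbalanced(25, 6, n_features = 5, seed = 2)$dataset
    a <- spiderResample(d, k = 3, seed = 5)
    b <- spiderResample(d, k = 3, seed = 5)
    expect_identical(featureMatrix(a), featureMatrix(b))
    expect_identical(a@synthesis, b@synthesis)
    c2 <- spiderResample(d, k = 3, seed = 6)
    expect_false(identical(a@synthesis$u, c2@synthesis$u))
})

test_that("degenerate resampling inputs are rejected", {
    single <- LabeledDataset(matrix(rnorm(20), 10, 2), rep(0L, 10))
    expect_error(spiderResample(single, 3, 1), "both classes")
    # minority samples buried inside the majority cloud are all noisy
    set.seed(4)
    maj <- matrix(rnorm(60, sd = 0.1), 30, 2)
    minr <- matrix(rnorm(6, sd = 0.1), 3, 2)
    d <- LabeledDataset(rbind(maj, minr), c(rep(0L, 30), rep(1L, 3)))
    expect_error(spiderResample(d, 3, 1), "no seeds for amplification")
})

test_that("already balanced safe data is returned unchanged", {
    d <- LabeledDataset(rbind(matrix(rnorm(20), 10, 2),
                              matrix(rnorm(20, mean = 10), 10, 2)),
                        rep(c(0L, 1L), each = 10))
    rs <- spiderResample(d, k = 3, seed = 1)
    expect_identical(nrow(rs@synthesis), 0L)
    expect_identical(featureMatrix(rs), featureMatrix(d))
})

test_that("resampling raises minority recall of a downstream classifier", {
    gains <- vapply(1:10, function(seed) {
        sim <- makeImbalanced(135, 15, n_features = 10, n_informative = 5,
                              effect = 2.0, seed = seed)
        sp <- stratifiedSplit(sim$dataset, 0.25, seed = seed)
        recall <- function(train) {
            m <- fitBaseline(train, "rf", seed = seed)
            pred <- as.integer(predictProba(m, featureMatrix(sp@test))[, "1"]
                               >= 0.5)
            truth <- classLabels(sp@test)
            if (sum(truth == 1L) == 0) return(NA_real_)
            sum(pred == 1L & truth == 1L) / sum(truth == 1L)
        }
        bal <- spiderResample(sp@train, k = 3, seed = seed)@dataset
        recall(bal) - recall(sp@train)
    }, numeric(1))
    expect_gt(mean(gains, na.rm = TRUE), 0)
})
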