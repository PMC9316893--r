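#' Draw a class-balanced, weight-proportional subset
#'
#' Draws \code{per_class_size} samples from each class with probability
#' proportional to the per-sample weights: without replacement when the
#' class has at least \code{per_class_size} members, with replacement
#' otherwise.  When a class is drawn exhaustively under uniform weights the
#' draw is the identity (original order), which keeps single-round
#' committees exactly equivalent to their directly trained base learner.
#'
#' @param data a two-class \linkS4class{LabeledDataset}.
#' @param sample_weights nonnegative per-sample weights; each class must
#'   have positive total weight.
#' @param per_class_size samples to draw per class.
#' @param rng_seed integer seed; the draw is deterministic given it.
#' @return The subset as a \linkS4class{LabeledDataset} (sample ids are
#'   made unique when drawing with replacement).
#' @export
drawBalancedSubset <- function(data, sample_weights, per_class_size,
                               rng_seed = 1L) {
    stopIfSingleClass(data, "balanced subset drawing")
    per_class_size <- as.integer(per_class_size)
    stopifnot(per_class_size >= 1L)
    if (length(sample_weights) != nSamples(data))
        stop("one weight per sample required", call. = FALSE)
    if (any(sample_weights < 0))
        stop("weights must be nonnegative", call. = FALSE)
    idx <- withSeed(rng_seed, {
        unlist(lapply(c(0L, 1L), function(cls) {
            ci <- which(data@labels == cls)
            w <- sample_weights[ci]
            if (sum(w) <= 0)
                stop("zero total weight in class ", cls, call. = FALSE)
            uniform <- diff(range(w)) == 0
            if (length(ci) == per_class_size && uniform) return(ci)
            # with replacement when the class (or its positive-weight
            # support) is smaller than the requested subset
            replace <- length(ci) < per_class_size ||
                sum(w > 0) < per_class_size
            ci[sample.int(length(ci), per_class_size, replace = replace,
                          prob = w)]
        }))
    })
    feat <- data@features[idx, , drop = FALSE]
    rownames(feat) <- make.unique(rownames(feat))
    new("LabeledDataset", features = feat, labels = data@labels[idx])
}

# ---- base-learner fitting / prediction wrappers -------------------------

svmGamma <- function(spec, x) {
    if (is.finite(spec@svm_gamma)) return(spec@svm_gamma)
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v <= 0) v <- 1
    1 / (ncol(x) * v)
}

# Platt-style sigmoid calibration of SVM decision values on a stratified
# 20% holdout of the training subset; degenerate fits fall back to a
# unit-scale sigmoid.
fitCalibratedSvm <- function(spec, sub, member_seed) {
    x <- sub@features; y <- sub@labels
    hold <- withSeed(childSeed(member_seed, 1), {
        unlist(lapply(c(0L, 1L), function(cls) {
            ci <- which(y == cls)
            nh <- max(1L, floor(0.2 * length(ci)))
            if (length(ci) - nh < 1L) nh <- length(ci) - 1L
            if (nh < 1L) integer() else sample(ci, nh)
        }))
    })
    fit_idx <- setdiff(seq_len(nrow(x)), hold)
    if (length(unique(y[fit_idx])) < 2L) { fit_idx <- seq_len(nrow(x)); hold <- integer() }
    kern <- if (spec@svm_kernel == "rbf") "radial" else "linear"
    gam <- svmGamma(spec, x)
    model <- e1071::svm(x[fit_idx, , drop = FALSE],
                        factor(y[fit_idx], levels = c(0L, 1L)),
                        kernel = kern, cost = spec@svm_C, gamma = gam,
                        scale = FALSE)
    decisionFor <- function(m, newx) {
        dv <- attr(stats::predict(m, newx, decision.values = TRUE),
                   "decision.values")
        # colname "A/B": positive decision value favors class A
        pos_first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        if (pos_first == "1") drop(dv) else -drop(dv)
    }
    coefs <- c(0, 1)  # sigmoid fallback: p1 = plogis(dv)
    if (length(hold) >= 2L && length(unique(y[hold])) == 2L) {
        dv_h <- decisionFor(model, x[hold, , drop = FALSE])
        cal <- suppressWarnings(
            stats::glm(y[hold] ~ dv_h, family = stats::binomial()))
        cf <- stats::coef(cal)
        if (all(is.finite(cf)) && abs(cf[2]) < 1e4 && cf[2] > 0)
            coefs <- unname(cf)
    }
    structure(list(model = model, coefs = coefs, decisionFor = decisionFor),
              class = "spiderSvmMember")
}

fitMember <- function(spec, sub, member_seed) {
    if (spec@family == "random_forest") {
        mtry <- min(spec@rf_features_per_tree, nFeatures(sub))
        model <- withSeed(member_seed,
            randomForest::randomForest(sub@features,
                factor(sub@labels, levels = c(0L, 1L)),
                ntree = spec@rf_trees, mtry = mtry))
        structure(list(model = model), class = "spiderRfMember")
    } else if (spec@family == "svm") {
        fitCalibratedSvm(spec, sub, member_seed)
    } else {
        booster <- withSeed(member_seed, {
            dtrain <- xgboost::xgb.DMatrix(sub@features, label = sub@labels,
                                           nthread = 1)
            xgboost::xgb.train(
                params = list(objective = "binary:logistic", max_depth = 3L,
                              eta = 0.1, nthread = 1,
                              seed = as.integer(member_seed)),
                data = dtrain, nrounds = 100L)
        })
        structure(list(model = booster, features = featNames(sub)),
                  class = "spiderGbtMember")
    }
}

memberProba <- function(member, features) {
    p1 <- if (inherits(member, "spiderRfMember")) {
        stats::predict(member$model, features, type = "prob")[, "1"]
    } else if (inherits(member, "spiderSvmMember")) {
        dv <- member$decisionFor(member$model, features)
        stats::plogis(member$coefs[1] + member$coefs[2] * dv)
    } else {
        stats::predict(member$model,
                       xgboost::xgb.DMatrix(features, nthread = 1))
    }
    p1 <- pmin(pmax(as.numeric(p1), 0), 1)
    cbind("0" = 1 - p1, "1" = p1)
}

#' Fit an AdaBoost-style committee of one base-learner family
#'
#' Samples start equally weighted.  Each round draws a class-balanced
#' subset with probability proportional to the current weights, fits one
#' base learner on it, predicts the whole training population, and computes
#' the weighted training error eps.  A member with eps >= 0.5 is discarded
#' and redrawn (at most 3 retries per round, then boosting stops early);
#' otherwise its vote weight is alpha = 0.5*log((1 - eps)/eps) (eps clipped
#' to [1e-6, 1 - 1e-6]), misclassified samples are up-weighted by
#' exp(alpha), and weights are renormalized.  A round with zero raw
#' training error ends the loop: later members could not improve on it.
#'
#' @param spec a \linkS4class{BaseLearnerSpec}.
#' @param data the two-class boosting population.
#' @param rounds maximum number of members.
#' @param per_class_size balanced-subset size per class; default the
#'   minority-class count.
#' @param seed integer seed.
#' @return A \linkS4class{BoostedCommittee}.
#' @export
boostFit <- function(spec, data, rounds = 10L, per_class_size = NULL,
                     seed = 1L) {
    stopIfSingleClass(data, "boosting")
    stopIfMissingValues(data, "boosting")
    rounds <- as.integer(rounds)
    n <- nSamples(data)
    if (is.null(per_class_size))
        per_class_size <- min(sum(data@labels == 0L), sum(data@labels == 1L))
    w <- rep(1 / n, n)
    members <- list(); alphas <- numeric()
    eps_tol <- 1e-9
    for (r in seq_len(rounds)) {
        fitted <- FALSE
        for (try in 0:3) {
            draw_seed <- childSeed(seed, 10L * r + try)
            sub <- drawBalancedSubset(data, w, per_class_size,
                                      rng_seed = draw_seed)
            member <- fitMember(spec, sub, member_seed = childSeed(seed, r))
            pred <- as.integer(memberProba(member, data@features)[, "1"] >= 0.5)
            mis <- pred != data@labels
            eps <- sum(w[mis])
            if (eps < 0.5) { fitted <- TRUE; break }
        }
        if (!fitted) {
            if (!length(members))
                stop("boosting failed to find weak learner", call. = FALSE)
            break
        }
        eps_c <- min(max(eps, 1e-6), 1 - 1e-6)
        alpha <- 0.5 * log((1 - eps_c) / eps_c)
        members[[length(members) + 1L]] <- member
        alphas <- c(alphas, alpha)
        if (eps < eps_tol) break  # perfect member; nothing left to correct
        w[mis] <- w[mis] * exp(alpha)
        w <- w / sum(w)
    }
    new("BoostedCommittee", members = members, member_weights = alphas,
        spec = spec, rounds = rounds, feature_names = featNames(data))
}

checkFeatureWidth <- function(feature_names, features) {
    if (ncol(features) != length(feature_names))
        stop("feature width does not match training (", ncol(features),
             " vs ", length(feature_names), ")", call. = FALSE)
    if (is.null(colnames(features))) colnames(features) <- feature_names
    features
}

#' @describeIn predictProba alpha-weighted average of member probabilities;
#'   weights are normalized to sum to one (uniform when all alphas are 0).
#' @export
setMethod("predictProba", "BoostedCommittee", function(object, features) {
    features <- checkFeatureWidth(object@feature_names, features)
    a <- object@member_weights
    a <- if (sum(a) > 0) a / sum(a) else rep(1 / length(a), length(a))
    out <- matrix(0, nrow(features), 2, dimnames = list(NULL, c("0", "1")))
    for (m in seq_along(object@members))
        out <- out + a[m] * memberProba(object@members[[m]], features)
    out / rowSums(out)
})

#' Fit the two-arm probability-voting ensemble
#'
#' Optionally applies the selective over-sampler first (originals plus
#' synthetics then form the boosting population), fits one boosted
#' committee per base-learner family (random forest and SVM, with derived
#' seeds; optionally a third gradient-boosted-tree arm), and combines them
#' by probability voting.
#'
#' @param data a two-class \linkS4class{LabeledDataset} (complete and
#'   normalized).
#' @param rounds boosting rounds per arm (default 10).
#' @param per_class_size balanced-subset size per class; default the
#'   minority count of the (resampled) population.
#' @param resample_first apply \code{\link{spiderResample}} before boosting
#'   (default TRUE).
#' @param k neighbor count for the resampler.
#' @param seed integer seed.
#' @param with_gbt_arm add a gradient-boosted-tree arm (default FALSE).
#' @param tie_rule tie resolution of \code{\link{predictEnsemble}}.
#' @param tune grid-search svm_C over {0.1, 1, 10} by internal 3-fold CV
#'   accuracy before fitting (default FALSE).
#' @return A \linkS4class{VotingEnsemble}.
#' @export
fitEnsemble <- function(data, rounds = 10L, per_class_size = NULL,
                        resample_first = TRUE, k = 3L, seed = 1L,
                        with_gbt_arm = FALSE, tie_rule = "minority",
                        tune = FALSE) {
    stopIfSingleClass(data, "ensemble training")
    stopIfMissingValues(data, "ensemble training")
    pop <- if (resample_first) spiderResample(data, k = k, seed = seed)@dataset
           else data
    svm_C <- if (tune) tuneSvmCost(pop, seed = seed) else 1
    specs <- list(
        BaseLearnerSpec("random_forest", seed = as.integer(seed)),
        BaseLearnerSpec("svm", svm_C = svm_C, seed = as.integer(seed) + 1L))
    if (with_gbt_arm)
        specs <- c(specs, BaseLearnerSpec("gbt", seed = as.integer(seed) + 2L))
    arms <- lapply(specs, function(sp)
        boostFit(sp, pop, rounds = rounds, per_class_size = per_class_size,
                 seed = sp@seed))
    new("VotingEnsemble", arms = arms, tie_rule = tie_rule,
        feature_names = featNames(data))
}

# small deterministic grid search replacing Bayesian tuning: svm_C over
# {0.1, 1, 10} scored by 3-fold stratified CV accuracy of a plain SVM
tuneSvmCost <- function(data, grid = c(0.1, 1, 10), seed = 1L) {
    folds <- withSeed(childSeed(seed, 99), {
        f <- integer(nSamples(data))
        for (cls in c(0L, 1L)) {
            ci <- sample(which(data@labels == cls))
            f[ci] <- rep_len(1:3, length(ci))
        }
        f
    })
    acc <- vapply(grid, function(C) {
        mean(vapply(1:3, function(fold) {
            tr <- data[folds != fold, ]; te <- data[folds == fold, ]
            if (length(unique(tr@labels)) < 2L || nSamples(te) == 0) return(NA_real_)
            spec <- BaseLearnerSpec("svm", svm_C = C)
            m <- fitCalibratedSvm(spec, tr, member_seed = childSeed(seed, fold))
            mean(as.integer(memberProba(m, te@features)[, "1"] >= 0.5) ==
                     te@labels)
        }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    grid[which.max(acc)]
}

#' @describeIn predictProba unweighted mean of the arms' probability pairs.
#' @export
setMethod("predictProba", "VotingEnsemble", function(object, features) {
    features <- checkFeatureWidth(object@feature_names, features)
    probs <- lapply(object@arms, predictProba, features = features)
    Reduce(`+`, probs) / length(probs)
})

#' Predict labels and probabilities from a voting ensemble
#'
#' Final probabilities are the unweighted mean of the arms'; the label is
#' the argmax, with an exact (0.5, 0.5) tie resolved by the ensemble's tie
#' rule (default: the minority/positive class).
#'
#' @param ensemble a \linkS4class{VotingEnsemble}.
#' @param features numeric matrix matching the training features.
#' @return list with \code{labels} (integer 0/1) and \code{proba}
#'   (n x 2 matrix).
#' @export
predictEnsemble <- function(ensemble, features) {
    proba <- predictProba(ensemble, features)
    labels <- as.integer(proba[, "1"] > proba[, "0"])
    ties <- proba[, "1"] == proba[, "0"]
    labels[ties] <- if (ensemble@tie_rule == "minority") 1L else 0L
    list(labels = labels, proba = proba)
}
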