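#' Generate an imbalanced two-class expression-like dataset
#'
#' Features are Gaussian with standard deviation \code{noise_sd}; the first
#' \code{n_informative} features have their minority-class (label 1) mean
#' shifted by \code{effect * noise_sd}.  Missing cells are placed
#' completely at random at rate \code{missing_rate}.  This mean-shift model
#' mirrors the structure the package's claims are tested against: a small
#' informative subset buried in noise features, with the class of interest
#' in the minority.
#'
#' @param n_majority,n_minority class sizes (majority = label 0); their
#'   ratio is the imbalance ratio.
#' @param n_features total features; \code{n_informative} of them carry
#'   the class signal.
#' @param n_informative number of shifted features (<= n_features).
#' @param effect minority mean shift in within-class SD units.
#' @param noise_sd within-class standard deviation.
#' @param missing_rate fraction of cells set missing, in [0, 1).
#' @param seed integer seed; fully deterministic.
#' @return list with \code{dataset} (a \linkS4class{LabeledDataset}) and
#'   \code{informative} (integer indices of the planted features).
#' @export
makeImbalanced <- function(n_majority, n_minority, n_features = 100L,
                           n_informative = min(10L, n_features),
                           effect = 2.0,
                           noise_sd = 1.0, missing_rate = 0, seed = 1L) {
    stopifnot(n_majority >= 1, n_minority >= 1, n_features >= 1,
              n_informative >= 0, n_informative <= n_features,
              effect >= 0, noise_sd > 0,
              missing_rate >= 0, missing_rate < 1)
    if (n_majority < n_minority)
        stop("config error: n_majority must be >= n_minority", call. = FALSE)
    n <- n_majority + n_minority
    labels <- c(rep(0L, n_majority), rep(1L, n_minority))
    mat <- withSeed(seed, {
        m <- matrix(stats::rnorm(n * n_features, sd = noise_sd),
                    n, n_features)
        if (n_informative > 0)
            m[labels == 1L, seq_len(n_informative)] <-
                m[labels == 1L, seq_len(n_informative), drop = FALSE] +
                effect * noise_sd
        if (missing_rate > 0) {
            nmiss <- round(missing_rate * length(m))
            m[sample.int(length(m), nmiss)] <- NA_real_
        }
        m
    })
    dimnames(mat) <- list(paste0("s", seq_len(n)),
                          paste0("g", seq_len(n_features)))
    list(dataset = new("LabeledDataset", features = mat, labels = labels),
         informative = seq_len(n_informative))
}

#' Write a synthetic KEEL-format fixture
#'
#' Generates a dataset with \code{\link{makeImbalanced}} (no missing cells)
#' and writes it as a KEEL \code{.dat} file that \code{\link{readKeel}}
#' reads back losslessly (counts and labels exact, values at 6 significant
#' digits).  Two writes with the same configuration are byte-identical.
#'
#' @param path output path.
#' @param ... passed to \code{\link{makeImbalanced}} (missing_rate forced
#'   to 0).
#' @return \code{path}, invisibly.
#' @export
makeKeelFixture <- function(path, ...) {
    args <- list(...)
    args$missing_rate <- 0
    sim <- do.call(makeImbalanced, args)
    writeKeel(sim$dataset, path)
}

#' Generate three-contrast stage data with planted DE genes
#'
#' Each contrast is two Gaussian groups of \code{n_per_group} samples over
#' the same \code{n_genes} genes (label 0 = reference, 1 = condition).
#' \code{planted_up_all3} genes get a \code{+effect} condition-group shift
#' in all three contrasts and \code{planted_down_all3} a \code{-effect}
#' shift; \code{extra_per_contrast} additional genes are shifted (up) in
#' one contrast only.  The truth sets are disjoint by construction.
#'
#' @param n_per_group samples per group per contrast.
#' @param n_genes total genes.
#' @param planted_up_all3,planted_down_all3 genes DE in all three
#'   contrasts.
#' @param extra_per_contrast genes DE in exactly one contrast.
#' @param effect mean shift in SD units.
#' @param seed integer seed.
#' @return list with \code{stages} (named list of three
#'   \linkS4class{LabeledDataset}) and \code{truth} (list of gene-name
#'   vectors: up_all3, down_all3, extras per contrast).
#' @export
makeStageData <- function(n_per_group = 30L, n_genes = 200L,
                          planted_up_all3 = 30L, planted_down_all3 = 0L,
                          extra_per_contrast = 0L, effect = 4.0, seed = 1L) {
    need <- planted_up_all3 + planted_down_all3 + 3L * extra_per_contrast
    if (need > n_genes)
        stop("config error: planted counts exceed n_genes", call. = FALSE)
    genes <- paste0("g", seq_len(n_genes))
    up_idx <- seq_len(planted_up_all3)
    down_idx <- seq_len(planted_down_all3) + planted_up_all3
    extra_idx <- lapply(1:3, function(ct)
        planted_up_all3 + planted_down_all3 +
            (ct - 1L) * extra_per_contrast + seq_len(extra_per_contrast))
    contrast_names <- c("control_vs_patient", "baseline_vs_year1",
                        "year1_vs_year2")
    stages <- withSeed(seed, {
        lapply(1:3, function(ct) {
            n <- 2L * n_per_group
            labels <- rep(c(0L, 1L), each = n_per_group)
            m <- matrix(stats::rnorm(n * n_genes), n, n_genes)
            cond <- labels == 1L
            if (length(up_idx))
                m[cond, up_idx] <- m[cond, up_idx, drop = FALSE] + effect
            if (length(down_idx))
                m[cond, down_idx] <- m[cond, down_idx, drop = FALSE] - effect
            ei <- extra_idx[[ct]]
            if (length(ei))
                m[cond, ei] <- m[cond, ei, drop = FALSE] + effect
            dimnames(m) <- list(paste0("c", ct, "s", seq_len(n)), genes)
            new("LabeledDataset", features = m, labels = labels)
        })
    })
    names(stages) <- contrast_names
    list(stages = stages,
         truth = list(up_all3 = genes[up_idx], down_all3 = genes[down_idx],
                      extras = lapply(extra_idx, function(i) genes[i])))
}
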