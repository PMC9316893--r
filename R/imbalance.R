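#' Euclidean distance between two feature vectors
#'
#' The kNN machinery throughout the resampler uses the conventional
#' Euclidean distance sqrt(sum((a_i - b_i)^2)).  Neighbor orderings are
#' identical under the squared form, so the flagging below does not depend
#' on the choice of root.
#'
#' @param a,b numeric vectors of equal length, no missing values.
#' @return nonnegative scalar distance.
#' @examples
#' pairwiseDistance(c(0, 0), c(3, 4))  # 5
#' @export
pairwiseDistance <- function(a, b) {
    if (length(a) != length(b))
        stop("vectors must have equal length", call. = FALSE)
    if (anyNA(a) || anyNA(b))
        stop("missing values not allowed in distance computation",
             call. = FALSE)
    sqrt(sum((a - b)^2))
}

# Full symmetric distance matrix with Inf on the diagonal so a sample is
# never its own neighbor.
distanceMatrix <- function(data) {
    d <- as.matrix(stats::dist(data@features, method = "euclidean"))
    diag(d) <- Inf
    d
}

# Indices of the k nearest neighbors of sample i among `pool` (excluding i),
# ties broken by lower sample index.
nearestNeighbors <- function(dmat, i, k, pool = seq_len(ncol(dmat))) {
    pool <- setdiff(pool, i)
    if (length(pool) < k)
        stop("not enough samples in the neighbor pool for k = ", k,
             call. = FALSE)
    ord <- pool[order(dmat[i, pool], pool)]
    ord[seq_len(k)]
}

#' Flag samples as safe or noisy by a kNN self-classification test
#'
#' A sample is \emph{safe} when the majority vote of its k nearest other
#' samples matches its own label, and \emph{noisy} otherwise.  Exact vote
#' ties (possible for even k) count as safe.  This is the noise-recognition
#' test of the selective over-sampler: noisy samples are later excluded
#' from synthesis.
#'
#' @param data a complete two-class \linkS4class{LabeledDataset} with at
#'   least k samples per class.
#' @param k number of neighbors (default 3).
#' @return data.frame with columns \code{sample_id}, \code{class} and
#'   \code{knn_flag} ("safe"/"noisy").
#' @export
knnFlag <- function(data, k = 3L) {
    stopIfMissingValues(data, "kNN flagging")
    k <- as.integer(k)
    if (k < 1L) stop("k must be positive", call. = FALSE)
    if (k >= nSamples(data))
        stop("k must be smaller than the number of samples", call. = FALSE)
    counts <- table(factor(data@labels, levels = c(0L, 1L)))
    if (any(counts < k))
        stop("each class must have at least k samples", call. = FALSE)
    dmat <- distanceMatrix(data)
    flags <- vapply(seq_len(nSamples(data)), function(i) {
        nn <- nearestNeighbors(dmat, i, k)
        own <- sum(data@labels[nn] == data@labels[i])
        if (own >= k - own) "safe" else "noisy"
    }, character(1))
    data.frame(sample_id = sampleIds(data), class = data@labels,
               knn_flag = flags, stringsAsFactors = FALSE)
}

#' Partition non-noisy minority samples into weak and strong
#'
#' After noisy samples are removed from the neighbor pool, a safe minority
#' sample whose k nearest remaining neighbors contain more majority than
#' minority samples is \emph{weak}; otherwise it is \emph{strong}.  Noisy
#' minority samples are \emph{excluded} (they seed no synthesis).  Weak
#' samples are the ones amplified most by \code{\link{spiderResample}}.
#'
#' @param data a complete two-class \linkS4class{LabeledDataset}.
#' @param flags output of \code{\link{knnFlag}} on the same data.
#' @param k number of neighbors used for the strength test.
#' @return \code{flags} with an added \code{strength} column
#'   ("weak"/"strong"/"excluded" for minority samples, NA for majority).
#' @export
partitionMinority <- function(data, flags, k = 3L) {
    stopIfMissingValues(data, "minority partition")
    k <- as.integer(k)
    dmat <- distanceMatrix(data)
    noisy <- flags$knn_flag == "noisy"
    pool <- which(!noisy)
    strength <- rep(NA_character_, nSamples(data))
    for (i in which(data@labels == 1L)) {
        if (noisy[i]) { strength[i] <- "excluded"; next }
        nn <- nearestNeighbors(dmat, i, k, pool = pool)
        nmaj <- sum(data@labels[nn] == 0L)
        strength[i] <- if (nmaj > k - nmaj) "weak" else "strong"
    }
    flags$strength <- strength
    flags
}

#' Selective kNN over-sampling of the minority class
#'
#' Implements the selective over-sampler: (1) flag every sample safe/noisy
#' by the kNN self-classification test and exclude noisy samples from the
#' neighbor pool used for synthesis (originals are retained in the output;
#' no under-sampling); (2) partition the remaining minority samples into
#' weak and strong; (3) each weak sample s generates c interpolated copies,
#' c = its number of majority samples among its k nearest pool neighbors,
#' and each strong sample generates one; every copy is
#' \code{s + u * (nu - s)} with \code{u ~ Uniform(0,1)} and \code{nu} drawn
#' uniformly from s's k nearest pool neighbors; (4) generation repeats over
#' the weak set until the minority count reaches
#' \code{ceiling(balance_target * majority count)}, capped at
#' \code{max_passes} passes.  Synthesis stops mid-pass the moment the
#' target is met, so the output imbalance ratio never drops below 1 by
#' construction and never exceeds the input's.
#'
#' @param data a complete two-class \linkS4class{LabeledDataset} with at
#'   least k samples per class (label 1 must be the minority/positive
#'   class).
#' @param k neighbor count (default 3).
#' @param seed integer seed; the result is fully deterministic given
#'   (data, k, seed).
#' @param balance_target target minority/majority ratio (default 1.0).
#' @param max_passes hard cap on generation passes over the weak set.
#' @param drop_noisy_majority if TRUE, noisy majority originals are removed
#'   from the returned dataset as well (default FALSE: they are only
#'   excluded from the neighbor pool, so no majority information is lost).
#' @return A \linkS4class{ResampleResult}.
#' @export
spiderResample <- function(data, k = 3L, seed = 1L, balance_target = 1.0,
                           max_passes = 10L, drop_noisy_majority = FALSE) {
    stopIfSingleClass(data, "resampling")
    stopIfMissingValues(data, "resampling")
    if (sum(data@labels == 1L) > sum(data@labels == 0L))
        stop("label 1 must be the minority class; remap labels first",
             call. = FALSE)
    k <- as.integer(k)
    flags <- knnFlag(data, k)
    flags <- partitionMinority(data, flags, k)
    noisy <- flags$knn_flag == "noisy"
    pool <- which(!noisy)

    seeds_weak <- which(flags$strength %in% "weak")
    seeds_strong <- which(flags$strength %in% "strong")
    if (!length(seeds_weak) && !length(seeds_strong))
        stop("no seeds for amplification: all minority samples are noisy",
             call. = FALSE)

    dmat <- distanceMatrix(data)
    nn_of <- lapply(seq_len(nSamples(data)), function(i) {
        if (data@labels[i] == 1L && !noisy[i])
            nearestNeighbors(dmat, i, k, pool = pool) else integer()
    })
    copies_weak <- vapply(seeds_weak, function(i)
        sum(data@labels[nn_of[[i]]] == 0L), integer(1))

    n_major <- sum(data@labels == 0L)
    target <- ceiling(balance_target * n_major)
    n_minor <- sum(data@labels == 1L)

    syn_feat <- list(); syn_rec <- list()
    synthesize <- function(i) {
        nu <- nn_of[[i]][sample.int(k, 1L)]
        u <- stats::runif(1)
        list(feat = data@features[i, ] +
                 u * (data@features[nu, ] - data@features[i, ]),
             parent = sampleIds(data)[i],
             neighbor = sampleIds(data)[nu], u = u)
    }
    withSeed(seed, {
        pass <- 0L
        repeat {
            if (n_minor >= target || pass >= max_passes) break
            pass <- pass + 1L
            # first pass amplifies both tiers; later passes revisit the weak set
            plan <- if (pass == 1L)
                c(rep(seeds_weak, times = copies_weak), seeds_strong)
            else rep(seeds_weak, times = copies_weak)
            plan <- sort(plan)
            if (!length(plan)) break
            for (i in plan) {
                if (n_minor >= target) break
                s <- synthesize(i)
                syn_feat[[length(syn_feat) + 1L]] <- s$feat
                syn_rec[[length(syn_rec) + 1L]] <-
                    data.frame(parent_id = s$parent, neighbor_id = s$neighbor,
                               u = s$u, stringsAsFactors = FALSE)
                n_minor <- n_minor + 1L
            }
        }
    })

    keep <- if (drop_noisy_majority)
        which(!(noisy & data@labels == 0L)) else seq_len(nSamples(data))
    nsyn <- length(syn_feat)
    feat <- data@features[keep, , drop = FALSE]
    labels <- data@labels[keep]
    prov <- rep("original", length(keep))
    syn_ids <- character(0)
    if (nsyn > 0) {
        smat <- do.call(rbind, syn_feat)
        syn_ids <- paste0("syn", seq_len(nsyn))
        rownames(smat) <- syn_ids
        feat <- rbind(feat, smat)
        labels <- c(labels, rep(1L, nsyn))
        prov <- c(prov, rep("synthetic", nsyn))
    }
    synthesis <- if (nsyn > 0)
        cbind(data.frame(sample_id = syn_ids, stringsAsFactors = FALSE),
              do.call(rbind, syn_rec))
    else data.frame(sample_id = character(), parent_id = character(),
                    neighbor_id = character(), u = numeric(),
                    stringsAsFactors = FALSE)
    new("ResampleResult",
        dataset = new("LabeledDataset", features = feat,
                      labels = as.integer(labels)),
        flags = flags, provenance = prov, synthesis = synthesis,
        seed = as.integer(seed))
}

#' Write the per-sample flags of a ResampleResult as TSV
#'
#' Columns: sample_id, class, knn_flag, strength, provenance; original
#' samples first, then synthetics (whose flag columns are empty).
#'
#' @param result a \linkS4class{ResampleResult}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResampleFlags <- function(result, path) {
    orig <- result@flags
    orig$provenance <- "original"
    syn <- result@synthesis
    if (nrow(syn)) {
        syn_rows <- data.frame(sample_id = syn$sample_id, class = 1L,
                               knn_flag = "", strength = "",
                               provenance = "synthetic",
                               stringsAsFactors = FALSE)
        orig <- rbind(orig, syn_rows)
    }
    utils::write.table(orig, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
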