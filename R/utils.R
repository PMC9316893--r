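# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG state without disturbing the caller's
# stream; every exported stochastic operation routes its randomness through
# this so results are reproducible from the seed argument alone.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a child seed from a parent seed and a small stride, staying well
# inside 32-bit integer range.
childSeed <- function(seed, offset) {
    as.integer((as.double(seed) + 104729 * offset) %% 2147483647)
}

stopIfMissingValues <- function(data, what) {
    if (anyNA(data@features))
        stop(what, " requires a complete matrix; impute missing values first",
             call. = FALSE)
}

stopIfSingleClass <- function(data, what) {
    if (length(unique(data@labels)) < 2L)
        stop(what, " requires both classes to be present", call. = FALSE)
}

# Format numerics as fixed 6-significant-digit text so all writers are
# byte-stable across runs and platforms.
formatNum <- function(x) {
    out <- formatC(x, digits = 6, format = "g", flag = "")
    out[is.na(x)] <- "NA"
    out
}

minorityLabel <- function(labels) {
    # positive class is 1 by construction; helper kept for readability
    if (sum(labels == 1L) <= sum(labels == 0L)) 1L else 0L
}
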