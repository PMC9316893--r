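#' Read a labeled expression CSV
#'
#' The expression-CSV dialect is: comma-separated, UTF-8, first row a header,
#' one column holding the class label, all remaining columns numeric
#' features.  Empty cells and the token \code{"NA"} are read as missing
#' values and carried as \code{NA} in the matrix.
#'
#' @param path path to the CSV file.
#' @param label_column name of the label column.
#' @param label_map named numeric vector mapping label tokens to 0/1.  The
#'   default maps \code{"control"} and \code{"0"} to 0, \code{"patient"} and
#'   \code{"1"} to 1.
#' @return A \linkS4class{LabeledDataset}.  Row ids come from an \code{id}
#'   column when present, otherwise row numbers.
#' @export
readExpressionCsv <- function(path, label_column = "class",
                              label_map = c(control = 0, patient = 1,
                                            "0" = 0, "1" = 1)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character",
                          na.strings = c("", "NA"))
    if (!label_column %in% names(df))
        stop("format error: label column '", label_column, "' not found",
             call. = FALSE)
    tokens <- df[[label_column]]
    bad <- !tokens %in% names(label_map)
    if (any(bad))
        stop("format error: unmapped label token(s): ",
             paste(unique(tokens[bad]), collapse = ", "), call. = FALSE)
    labels <- as.integer(label_map[tokens])
    ids <- if ("id" %in% names(df) && "id" != label_column) df[["id"]]
           else as.character(seq_len(nrow(df)))
    featcols <- setdiff(names(df), c(label_column, "id"))
    mat <- matrix(NA_real_, nrow(df), length(featcols),
                  dimnames = list(ids, featcols))
    for (j in seq_along(featcols)) {
        col <- df[[featcols[j]]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(!is.na(col) & is.na(num))
        if (length(bad))
            stop("format error: non-numeric value '", col[bad[1]],
                 "' at row ", bad[1], ", column '", featcols[j], "'",
                 call. = FALSE)
        mat[, j] <- num
    }
    LabeledDataset(mat, labels)
}

#' Write a LabeledDataset as expression CSV
#'
#' Emits the same dialect \code{\link{readExpressionCsv}} reads, with values
#' printed at 6 significant digits so output is byte-stable.
#'
#' @param data a \linkS4class{LabeledDataset}.
#' @param path output path.
#' @param label_column name for the label column.
#' @param label_tokens length-2 character, tokens written for classes 0 and
#'   1 respectively.
#' @return \code{path}, invisibly.
#' @export
writeExpressionCsv <- function(data, path, label_column = "class",
                               label_tokens = c("0", "1")) {
    mat <- data@features
    lines <- c(paste(c("id", label_column, colnames(mat)), collapse = ","),
               vapply(seq_len(nrow(mat)), function(i) {
                   paste(c(rownames(mat)[i],
                           label_tokens[data@labels[i] + 1L],
                           formatNum(mat[i, ])), collapse = ",")
               }, character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Read a KEEL-format .dat file
#'
#' Parses the \code{@relation}/\code{@attribute}/\code{@data} dialect used
#' by the KEEL imbalanced-dataset repository.  The last attribute is the
#' class; exactly two class tokens are supported.  The minority class is
#' mapped to label 1 and the majority to 0, so that "positive" always means
#' minority regardless of the file's own token names (ties in class size map
#' the second declared token to 1).
#'
#' @param path path to the .dat file.
#' @return A \linkS4class{LabeledDataset}.
#' @export
readKeel <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    lower <- tolower(lines)
    if (!any(startsWith(lower, "@relation")))
        stop("format error: missing @relation header", call. = FALSE)
    datapos <- which(startsWith(lower, "@data"))
    if (length(datapos) != 1L)
        stop("format error: expected exactly one @data section", call. = FALSE)
    attrlines <- lines[startsWith(lower, "@attribute")]
    if (length(attrlines) < 2L)
        stop("format error: need at least one feature and a class attribute",
             call. = FALSE)
    attrnames <- vapply(attrlines, function(l) {
        strsplit(sub("^@attribute\\s+", "", l, ignore.case = TRUE),
                 "[[:space:]{]")[[1]][1]
    }, character(1), USE.NAMES = FALSE)
    rows <- lines[(datapos + 1L):length(lines)]
    rows <- rows[!startsWith(rows, "@")]
    if (!length(rows)) stop("format error: empty @data section", call. = FALSE)
    cells <- strsplit(rows, ",")
    ncol_exp <- length(attrnames)
    if (any(lengths(cells) != ncol_exp))
        stop("format error: data row width does not match attribute count",
             call. = FALSE)
    cells <- lapply(cells, trimws)
    classtok <- vapply(cells, function(r) r[ncol_exp], character(1))
    toks <- unique(classtok)
    if (length(toks) > 2L)
        stop("unsupported format: more than two class tokens: ",
             paste(toks, collapse = ", "), call. = FALSE)
    if (length(toks) == 1L) {
        minority_tok <- NA_character_  # single-class file: all labels 0
    } else {
        counts <- table(factor(classtok, levels = toks))
        # minority token -> 1; on a tie the later-observed token is positive
        minority_tok <- if (counts[1] < counts[2]) toks[1] else toks[2]
    }
    feat <- matrix(NA_real_, length(rows), ncol_exp - 1L,
                   dimnames = list(as.character(seq_along(rows)),
                                   attrnames[-ncol_exp]))
    for (j in seq_len(ncol_exp - 1L)) {
        col <- vapply(cells, `[`, character(1), j)
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num) & col != "NA" & col != "?")
        if (length(bad))
            stop("format error: non-numeric value '", col[bad[1]],
                 "' in attribute '", attrnames[j], "'", call. = FALSE)
        feat[, j] <- num
    }
    labels <- if (is.na(minority_tok)) rep(0L, length(classtok))
              else as.integer(classtok == minority_tok)
    LabeledDataset(feat, labels)
}

#' Write a LabeledDataset as a KEEL .dat file
#'
#' @param data a \linkS4class{LabeledDataset}.
#' @param path output path.
#' @param relation relation name for the header.
#' @param class_tokens tokens written for classes 0 and 1.
#' @return \code{path}, invisibly.
#' @export
writeKeel <- function(data, path, relation = "synthetic",
                      class_tokens = c("negative", "positive")) {
    mat <- data@features
    header <- c(paste0("@relation ", relation),
                paste0("@attribute ", colnames(mat), " real"),
                paste0("@attribute class {", class_tokens[1], ", ",
                       class_tokens[2], "}"),
                "@data")
    body <- vapply(seq_len(nrow(mat)), function(i) {
        paste(c(formatNum(mat[i, ]), class_tokens[data@labels[i] + 1L]),
              collapse = ",")
    }, character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Impute missing values by within-class feature means
#'
#' Each missing cell is replaced by the mean of the non-missing values of
#' that feature within the sample's own class.  A feature entirely missing
#' within a class falls back to the overall feature mean; a feature missing
#' everywhere is filled with 0 (with a warning).  Non-missing cells are
#' never altered, so the operation is idempotent.
#'
#' @param data a \linkS4class{LabeledDataset}.
#' @return The imputed \linkS4class{LabeledDataset}.
#' @export
imputeClassMean <- function(data) {
    mat <- data@features
    if (!anyNA(mat)) return(data)
    for (j in which(colSums(is.na(mat)) > 0)) {
        col <- mat[, j]
        overall <- mean(col, na.rm = TRUE)
        if (is.nan(overall)) {
            warning("feature '", colnames(mat)[j],
                    "' has no observed values; filled with 0")
            mat[, j] <- 0
            next
        }
        for (cls in unique(data@labels)) {
            inc <- data@labels == cls
            miss <- inc & is.na(col)
            if (!any(miss)) next
            m <- mean(col[inc], na.rm = TRUE)
            mat[miss, j] <- if (is.nan(m)) overall else m
        }
    }
    new("LabeledDataset", features = mat, labels = data@labels)
}

#' Per-feature min-max normalization parameters
#'
#' @param data a complete (imputed) \linkS4class{LabeledDataset}.
#' @return list with numeric vectors \code{min} and \code{max} per feature.
#' @export
minmaxParams <- function(data) {
    stopIfMissingValues(data, "normalization")
    list(min = apply(data@features, 2, min),
         max = apply(data@features, 2, max))
}

#' Apply min-max normalization with given parameters
#'
#' Maps each feature through (x - min)/(max - min) and clips to [0,1], so
#' parameters learned on a training split can be applied to test samples
#' without leakage.  Constant features (max == min) map to all-zeros.
#'
#' @param data a complete \linkS4class{LabeledDataset}.
#' @param params output of \code{\link{minmaxParams}}.
#' @return The normalized \linkS4class{LabeledDataset}.
#' @export
applyMinmax <- function(data, params) {
    stopIfMissingValues(data, "normalization")
    rng <- params$max - params$min
    mat <- sweep(data@features, 2, params$min, "-")
    safe <- ifelse(rng > 0, rng, 1)
    mat <- sweep(mat, 2, safe, "/")
    mat[, rng == 0] <- 0
    mat[mat < 0] <- 0
    mat[mat > 1] <- 1
    new("LabeledDataset", features = mat, labels = data@labels)
}

#' Min-max normalize each feature to [0,1]
#'
#' Convenience wrapper fitting and applying \code{\link{minmaxParams}} on
#' the same data.  Idempotent: a second application is the identity.
#'
#' @param data a complete \linkS4class{LabeledDataset}.
#' @return The normalized \linkS4class{LabeledDataset}.
#' @export
normalizeMinmax <- function(data) applyMinmax(data, minmaxParams(data))

#' Stratified train/test split
#'
#' Deterministic given the seed; per-class test counts are
#' \code{round(test_fraction * n_class)} clamped so both partitions keep at
#' least one sample of each class (within one sample of the stratified
#' ideal).
#'
#' @param data a \linkS4class{LabeledDataset} with at least two samples per
#'   class.
#' @param test_fraction fraction of each class assigned to the test set.
#' @param seed integer seed.
#' @return A \linkS4class{SplitResult}.
#' @export
stratifiedSplit <- function(data, test_fraction = 0.2, seed = 1L) {
    stopifnot(test_fraction > 0, test_fraction < 1)
    counts <- table(factor(data@labels, levels = c(0L, 1L)))
    if (any(counts < 2L))
        stop("stratified split requires at least 2 samples per class",
             call. = FALSE)
    test_idx <- withSeed(seed, {
        unlist(lapply(c(0L, 1L), function(cls) {
            idx <- which(data@labels == cls)
            ntest <- min(max(round(test_fraction * length(idx)), 1L),
                         length(idx) - 1L)
            sort(sample(idx, ntest))
        }))
    })
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_len(nSamples(data)), test_idx)
    new("SplitResult", train = data[train_idx, ], test = data[test_idx, ],
        seed = as.integer(seed))
}
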