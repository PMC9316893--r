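writeCsvFixture <- function(lines) {
    path <- withr::local_tempfile(fileext = ".csv",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

test_that("expression CSV parsing maps labels, ids and missing cells", {
    path <- writeCsvFixture(c(
        "id,class,g1,g2,g3",
        "a,control,1.5,2,3",
        "b,patient,4,NA,6",
        "c,control,7,8,",
        "d,patient,10,11,12"))
    d <- readExpressionCsv(path, "class")
    expect_s4_class(d, "LabeledDataset")
    expect_identical(classLabels(d), c(0L, 1L, 0L, 1L))
    expect_identical(sampleIds(d), c("a", "b", "c", "d"))
    expect_identical(featNames(d), c("g1", "g2", "g3"))
    # one "NA" token and one empty cell -> exactly two missing markers
    expect_identical(which(is.na(featureMatrix(d))),
                     which(is.na(matrix(c(1.5, 4, 7, 10, 2, NA, 8, 11,
                                          3, 6, NA, 12), 4, 3))))
})

test_that("expression CSV format errors are specific", {
    path <- writeCsvFixture(c("id,g1", "a,1"))
    expect_error(readExpressionCsv(path, "class"), "label column")
    path2 <- writeCsvFixture(c("id,class,g1", "a,control,oops"))
    expect_error(readExpressionCsv(path2, "class"), "row 1.*column 'g1'")
    path3 <- writeCsvFixture(c("id,class,g1", "a,sick,1"))
    expect_error(readExpressionCsv(path3, "class"), "unmapped label")
})

test_that("expression CSV round-trips through the writer", {
    d <- makeImbalanced(6, 3, n_features = 4, seed = 5)$dataset
    path <- withr::local_tempfile(fileext = ".csv")
    writeExpressionCsv(d, path)
    d2 <- readExpressionCsv(path, "class")
    expect_identical(classLabels(d2), classLabels(d))
    expect_identical(featNames(d2), featNames(d))
    expect_equal(featureMatrix(d2), featureMatrix(d), tolerance = 1e-5)
})

keelFixture <- function(class_col = c("negative", "negative", "negative",
                                      "negative", "positive", "positive")) {
    c("@relation toy",
      "@attribute f1 real",
      "@attribute f2 real",
      paste0("@attribute class {negative, positive}"),
      "@data",
      paste(seq_along(class_col), rev(seq_along(class_col)), class_col,
            sep = ","))
}

test_that("KEEL reader maps the minority class to label 1", {
    path <- writeCsvFixture(keelFixture())
    d <- readKeel(path)
    expect_identical(classLabels(d), c(0L, 0L, 0L, 0L, 1L, 1L))
    expect_identical(featNames(d), c("f1", "f2"))
    # swapped class frequencies invert the mapping: minority is still 1
    path2 <- writeCsvFixture(keelFixture(c("positive", "positive",
                                           "positive", "positive",
                                           "negative", "negative")))
    d2 <- readKeel(path2)
    expect_identical(classLabels(d2), c(0L, 0L, 0L, 0L, 1L, 1L))
})

test_that("KEEL format errors are detected", {
    lines <- keelFixture()
    expect_error(readKeel(writeCsvFixture(lines[-5])), "@data")
    expect_error(readKeel(writeCsvFixture(lines[-1])), "@relation")
    bad <- c(lines[1:3], "@attribute class {a, b, c}", "@data",
             "1,2,a", "2,3,b", "3,4,c")
    expect_error(readKeel(writeCsvFixture(bad)), "two class tokens")
})

test_that("class-mean imputation follows the fallback ladder", {
    mat <- matrix(c(1, NA, 3, 10,
                    5, 5, 5, NA), ncol = 2,
                  dimnames = list(letters[1:4], c("g1", "g2")))
    d <- LabeledDataset(mat, c(0L, 0L, 0L, 1L))
    imp <- imputeClassMean(d)
    # class-0 mean of g1 over observed cells (1, 3) = 2
    expect_equal(featureMatrix(imp)["b", "g1"], 2)
    # g2 entirely missing in class 1 -> overall mean 5
    expect_equal(featureMatrix(imp)["d", "g2"], 5)
    # untouched cells and idempotence
    expect_equal(featureMatrix(imp)[c("a", "c", "d"), "g1"], mat[c(1, 3, 4), 1])
    expect_identical(imputeClassMean(imp), imp)
})

test_that("fully missing features are zero-filled with a warning", {
    d <- LabeledDataset(matrix(c(1, 2, NA, NA), 2, 2,
                               dimnames = list(c("a", "b"), c("g1", "g2"))),
                        c(0L, 1L))
    expect_warning(imp <- imputeClassMean(d), "no observed values")
    expect_equal(unname(featureMatrix(imp)[, "g2"]), c(0, 0))
})

test_that("min-max normalization is bounded, constant-safe and idempotent", {
    d <- LabeledDataset(cbind(a = c(2, 4, 6), b = c(7, 7, 7),
                              c = c(0, 0.25, 1)),
                        c(0L, 0L, 1L))
    norm <- normalizeMinmax(d)
    expect_equal(unname(featureMatrix(norm)[, "a"]), c(0, 0.5, 1))
    expect_equal(unname(featureMatrix(norm)[, "b"]), c(0, 0, 0))
    expect_equal(featureMatrix(norm)[, "c"], featureMatrix(d)[, "c"])
    expect_identical(featureMatrix(normalizeMinmax(norm)),
                     featureMatrix(norm))
    expect_true(all(featureMatrix(norm) >= 0 & featureMatrix(norm) <= 1))
    dmiss <- LabeledDataset(cbind(a = c(1, NA)), c(0L, 1L))
    expect_error(normalizeMinmax(dmiss), "impute")
})

test_that("train-fitted normalization clips test values into [0,1]", {
    train <- LabeledDataset(cbind(g = c(0, 10)), c(0L, 1L))
    test <- LabeledDataset(cbind(g = c(-5, 5, 15)), c(0L, 0L, 1L))
    out <- applyMinmax(test, minmaxParams(train))
    expect_equal(unname(featureMatrix(out)[, 1]), c(0, 0.5, 1))
})

test_that("stratified split preserves class proportions and is seeded", {
    d <- makeImbalanced(80, 20, n_features = 3, seed = 1)$dataset
    sp <- stratifiedSplit(d, 0.2, seed = 9)
    expect_identical(sum(classLabels(sp@test) == 0L), 16L)
    expect_identical(sum(classLabels(sp@test) == 1L), 4L)
    expect_length(intersect(sampleIds(sp@train), sampleIds(sp@test)), 0)
    expect_setequal(c(sampleIds(sp@train), sampleIds(sp@test)), sampleIds(d))
    sp2 <- stratifiedSplit(d, 0.2, seed = 9)
    expect_identical(sampleIds(sp2@test), sampleIds(sp@test))
    sp3 <- stratifiedSplit(d, 0.2, seed = 10)
    expect_false(identical(sampleIds(sp3@test), sampleIds(sp@test)))
})

test_that("stratified split rejects classes with fewer than two samples", {
    d <- makeImbalanced(9, 1, n_features = 2, seed = 1)$dataset
    expect_error(stratifiedSplit(d, 0.2, seed = 1), "at least 2 samples")
})
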