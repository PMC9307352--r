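test_that("generator produces the configured shape and DE truth", {
    me <- simulateMicroarray(syntheticConfig(nGenes = 2000, nPerClass = 50,
                                             deFraction = 0.1, seed = 7))
    expect_s4_class(me, "MicroarrayExperiment")
    expect_equal(dim(me), c(2000L, 100L))
    expect_equal(sum(deTruth(me)), 200L)
    expect_equal(as.vector(table(classLabels(me))), c(50L, 50L))
    expect_true(all(exprsValues(me) > 0))
})

test_that("generation is a pure function of the configuration", {
    cfg <- syntheticConfig(nGenes = 150, nPerClass = 8, seed = 11)
    a <- simulateMicroarray(cfg)
    b <- simulateMicroarray(cfg)
    expect_identical(exprsValues(a), exprsValues(b))
    expect_identical(deTruth(a), deTruth(b))
    c <- simulateMicroarray(syntheticConfig(nGenes = 150, nPerClass = 8,
                                            seed = 12))
    expect_false(identical(exprsValues(a), exprsValues(c)))
    # caller RNG state untouched
    set.seed(99); before <- rnorm(1)
    set.seed(99); simulateMicroarray(cfg); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("invalid configurations name the offending field", {
    expect_error(syntheticConfig(nGenes = 0), "nGenes")
    expect_error(syntheticConfig(deFraction = 1.2), "deFraction")
    expect_error(syntheticConfig(noiseSd = 0), "noiseSd")
    expect_error(syntheticConfig(tailDf = 2), "tailDf")
})

test_that("zero effect size gives null-calibrated flagged genes", {
    # flagged genes carry no true shift, so per-gene t-tests behave as under
    # the null: empirical type-I rate at alpha = 0.05 is 0.05 +/- 0.02
    me <- simulateMicroarray(syntheticConfig(nGenes = 1000, nPerClass = 50,
                                             deFraction = 0.999,
                                             effectSize = 0, seed = 5))
    v <- exprsValues(me)
    lab <- classLabels(me)
    p <- apply(v, 1, function(r)
        stats::t.test(r[lab == 1], r[lab == 0])$p.value)
    rate <- mean(p < 0.05)
    expect_gt(rate, 0.03)
    expect_lt(rate, 0.07)
})

test_that("per-gene ANOVA power exceeds 0.9 at the calibration settings", {
    me <- simulateMicroarray(syntheticConfig(nGenes = 500, nPerClass = 50,
                                             deFraction = 0.2,
                                             effectSize = 2, noiseSd = 0.5,
                                             seed = 3))
    gs <- anovaVolcano(me)
    de <- deTruth(me) == 1L
    expect_gt(mean(gs@pValue[de] < 0.01), 0.9)
})

test_that("expression matrices round-trip through delimited text", {
    me <- tinyExperiment(nGenes = 10, nPerClass = 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpression(me, path)
    back <- readExpression(path)
    expect_equal(exprsValues(back), exprsValues(me), tolerance = 1e-12)
    expect_identical(classLabels(back), classLabels(me))
    expect_identical(rownames(back), rownames(me))
    # comma-delimited with sidecar labels
    p2 <- withr::local_tempfile(fileext = ".csv")
    pl <- withr::local_tempfile(fileext = ".csv")
    writeExpression(me, p2, sep = ",", labelsPath = pl)
    back2 <- readExpression(p2, labelsPath = pl)
    expect_equal(exprsValues(back2), exprsValues(me), tolerance = 1e-12)
    expect_identical(classLabels(back2), classLabels(me))
})

test_that("malformed expression files report the defect location", {
    me <- tinyExperiment(nGenes = 5, nPerClass = 3)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpression(me, path)
    lines <- readLines(path)
    bad <- strsplit(lines[5], "\t")[[1]]   # data row 3
    bad[3] <- "oops"                        # col 2 after gene_id
    writeLines(c(lines[1:4], paste(bad, collapse = "\t"), lines[6:7]),
               path)
    expect_error(readExpression(path), "row 3.*col 2")
    # missing labels entirely
    writeLines(lines[-2], path)
    expect_error(readExpression(path), "label")
    # ragged row
    writeLines(c(lines[1:3], paste(lines[4], "extra", sep = "\t"),
                 lines[5:7]), path)
    expect_error(readExpression(path), "ragged")
})
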