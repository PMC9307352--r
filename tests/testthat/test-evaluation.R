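test_that("metric report reproduces published benchmark rows", {
    m <- metricsFromConfusion(confusionMatrix(48, 44, 6, 2))
    expect_equal(round(as.numeric(m), 3),
                 c(92, 88.889, 92.308, 0.843, 0.924, 8, 85.714, 84.889))
    m2 <- metricsFromConfusion(confusionMatrix(46, 42, 8, 4))
    expect_equal(round(m2[["accuracy"]], 3), 88)
    expect_equal(round(m2[["precision"]], 3), 85.185)
    expect_equal(round(m2[["f1"]], 3), 88.462)
    expect_equal(round(m2[["mcc"]], 3), 0.762)
    expect_equal(round(m2[["csi"]], 3), 77.185)
    # perfect and chance classifiers
    perfect <- metricsFromConfusion(confusionMatrix(25, 25, 0, 0))
    expect_equal(unname(perfect[c("accuracy", "mcc", "jaccard")]),
                 c(100, 1, 100))
    chance <- metricsFromConfusion(confusionMatrix(25, 25, 25, 25))
    expect_equal(unname(chance[c("accuracy", "mcc")]), c(50, 0))
})

test_that("metric identities hold over random confusion matrices", {
    withr::with_seed(61, {
        for (rep in 1:200) {
            cts <- stats::rpois(4, lambda = sample(1:40, 1)) +
                c(1, 1, 0, 0)   # ensure positive total and tp, tn
            m <- metricsFromConfusion(confusionMatrix(cts[1], cts[2],
                                                      cts[3], cts[4]))
            expect_equal(m[["accuracy"]] + m[["error_rate"]], 100,
                         tolerance = 1e-9)
            f1 <- m[["f1"]] / 100
            expect_equal(m[["jaccard"]] / 100, f1 / (2 - f1),
                         tolerance = 1e-9)
            sen <- cts[1] / (cts[1] + cts[4])
            expect_equal(m[["fm"]], sqrt(m[["precision"]] / 100 * sen),
                         tolerance = 1e-9)
            expect_equal(m[["csi"]], m[["precision"]] + 100 * sen - 100,
                         tolerance = 1e-9)
            expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
            # flipping all predicted labels negates the MCC
            flip <- metricsFromConfusion(confusionMatrix(cts[4], cts[3],
                                                         cts[2], cts[1]))
            expect_equal(flip[["mcc"]], -m[["mcc"]], tolerance = 1e-9)
        }
    })
})

test_that("zero denominators yield flagged zeros", {
    m <- metricsFromConfusion(confusionMatrix(0, 10, 0, 0))
    expect_equal(unname(m[["precision"]]), 0)
    expect_true("precision" %in% attr(m, "flags"))
    expect_true("mcc" %in% attr(m, "flags"))
})

test_that("mse of scores matches brute-force sums", {
    expect_equal(mseScores(c(0.9, 0.1), c(0.9, 0.1)), 0)
    expect_equal(mseScores(rep(0.6, 5), rep(0.5, 5)), 0.01,
                 tolerance = 1e-12)
    withr::with_seed(62, {
        s <- runif(5); t <- runif(5)
    })
    expect_equal(mseScores(s, t), sum((s - t)^2) / 5, tolerance = 1e-12)
    expect_error(mseScores(1:3, 1:4), "equal length")
})

test_that("stratified folds partition samples with balanced classes", {
    lab <- rep(c(0L, 1L), each = 50)
    folds <- stratifiedFolds(lab, k = 10, seed = 4)
    expect_length(folds, 10)
    expect_identical(sort(unlist(folds)), 1:100)
    for (f in folds) {
        expect_length(f, 10)
        expect_equal(sum(lab[f]), 5)
    }
    # leave-one-out on tiny data: every sample tested exactly once
    lab2 <- rep(c(0L, 1L), 3)
    loo <- stratifiedFolds(lab2, k = 3, seed = 1)
    expect_identical(sort(unlist(loo)), 1:6)
    # different seeds: different assignment, same coverage
    f2 <- stratifiedFolds(lab, k = 10, seed = 5)
    expect_false(identical(folds, f2))
    expect_identical(sort(unlist(f2)), 1:100)
    expect_error(stratifiedFolds(lab, k = 60), "reduce k")
})

test_that("published tables are consistent with their confusion counts", {
    for (arm in c("none", "correlation")) {
        tab <- benchmarkTable(arm)
        expect_equal(nrow(tab), 30)
        audit <- auditMetricTable(tab, tab)
        expect_equal(nrow(audit), 0)
    }
})

test_that("the audit flags corrupted rows and accepts empty input", {
    tab <- benchmarkTable("none")
    tab$accuracy[7] <- tab$accuracy[7] + 0.5
    tab$mcc[12] <- tab$mcc[12] - 0.01
    audit <- auditMetricTable(tab, tab)
    expect_setequal(audit$row, c(7L, 12L))
    expect_setequal(audit$metric, c("accuracy", "mcc"))
    empty <- tab[0, ]
    expect_equal(nrow(auditMetricTable(empty, empty)), 0)
})

test_that("cross-validation pools fold confusions and records folds", {
    me <- simulateMicroarray(syntheticConfig(nGenes = 200, nPerClass = 10,
                                             effectSize = 3, seed = 6))
    res <- crossValidate(me, "DCT", "LR", k = 5, seed = 2)
    expect_s4_class(res, "CrossValidationResult")
    cm <- pooledConfusion(res)
    expect_equal(cm@tp + cm@tn + cm@fp + cm@fn, 20)
    fromFolds <- Reduce(`+`, lapply(res@foldConfusions, function(f)
        c(f@tp, f@tn, f@fp, f@fn)))
    expect_equal(fromFolds, c(cm@tp, cm@tn, cm@fp, cm@fn))
    expect_identical(sort(unlist(res@folds)), 1:20)
})

test_that("no stage sees test-fold data", {
    me <- simulateMicroarray(syntheticConfig(nGenes = 80, nPerClass = 6,
                                             seed = 8))
    labels <- classLabels(me)
    trainIdx <- 1:8
    testIdx <- 9:12
    mat <- exprsValues(me)
    mat2 <- mat
    mat2[, testIdx] <- mat2[, testIdx] * 5 + 1   # perturb test samples only
    # gene selection on training columns is unchanged
    g1 <- selectProminent(anovaVolcano(me[, trainIdx]), "fraction_by_p")
    me2 <- MicroarrayExperiment(mat2, labels = labels)
    g2 <- selectProminent(anovaVolcano(me2[, trainIdx]), "fraction_by_p")
    expect_identical(selectedGenes(g1), selectedGenes(g2))
    # FCM and SDA training-sample features are unchanged
    f1 <- fcmFeatures(mat, trainIdx = trainIdx, C = 3)
    f2 <- fcmFeatures(mat2, trainIdx = trainIdx, C = 3)
    expect_equal(featureValues(f1)[trainIdx, ],
                 featureValues(f2)[trainIdx, ], tolerance = 1e-12)
    s1 <- sdaFeatures(mat, labels, trainIdx = trainIdx, nFeatures = 4)
    s2 <- sdaFeatures(mat2, labels, trainIdx = trainIdx, nFeatures = 4)
    expect_equal(featureValues(s1)[trainIdx, ],
                 featureValues(s2)[trainIdx, ], tolerance = 1e-12)
    # correlation-distance selection on training rows is unchanged
    v1 <- t(mat); v2 <- t(mat2)
    sel1 <- selectByCorrelationDistance(v1, labels, k = 5,
                                        trainIdx = trainIdx)
    sel2 <- selectByCorrelationDistance(v2, labels, k = 5,
                                        trainIdx = trainIdx)
    expect_identical(sel1$keptIdx, sel2$keptIdx)
})
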