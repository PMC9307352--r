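test_that("per-gene ANOVA F equals the squared pooled t statistic", {
    me <- tinyExperiment(nGenes = 60, nPerClass = 6, seed = 2)
    gs <- anovaVolcano(me)
    v <- exprsValues(me)
    lab <- classLabels(me)
    tstat <- apply(v, 1, function(r)
        stats::t.test(r[lab == 1], r[lab == 0], var.equal = TRUE)$statistic)
    pref <- apply(v, 1, function(r)
        stats::t.test(r[lab == 1], r[lab == 0], var.equal = TRUE)$p.value)
    expect_equal(gs@fStat, unname(tstat^2), tolerance = 1e-9)
    expect_equal(gs@pValue, unname(pref), tolerance = 1e-9)
})

test_that("degenerate and separated genes follow the stated conventions", {
    v <- rbind(rep(1, 6),
               c(1, 1.1, 0.9, 10, 10.1, 9.9))
    me <- MicroarrayExperiment(v, labels = rep(c(0, 1), each = 3))
    gs <- anovaVolcano(me)
    expect_equal(gs@fStat[1], 0)
    expect_equal(gs@pValue[1], 1)
    expect_equal(gs@log2FoldChange[1], 0)
    expect_equal(gs@criterion$degenerate, 1L)
    expect_lt(gs@pValue[2], 1e-6)
    expect_equal(gs@log2FoldChange[2], log2(10), tolerance = 0.01)
})

test_that("selection modes keep the right genes with stable ordering", {
    p <- c(0.5, 0.01, 0.3, 0.02, 0.9, 0.02, 0.8, 0.1, 0.4, 0.6)
    lfc <- c(0, 3, 0, 1, 0, 2, 0, 0, 0, 0)
    gs <- new("GeneSelection", fStat = rep(1, 10), pValue = p,
              log2FoldChange = lfc, selectedIdx = integer(0),
              criterion = list())
    top3 <- selectProminent(gs, "top_k_by_p", k = 3)
    expect_identical(selectedGenes(top3), c(2L, 4L, 6L))
    # p tie at 0.02 between genes 4 and 6: |lfc| 2 beats 1 when k = 2
    top2 <- selectProminent(gs, "top_k_by_p", k = 2)
    expect_identical(selectedGenes(top2), c(2L, 6L))
    all10 <- selectProminent(gs, "top_k_by_p", k = 10)
    expect_identical(selectedGenes(all10), 1:10)
    expect_error(selectProminent(gs, "top_k_by_p", k = 11), "exceeds")
    thr <- selectProminent(gs, "thresholds", pMax = 0.05, fcMin = 1.5)
    expect_identical(selectedGenes(thr), c(2L, 6L))
    frac <- selectProminent(gs, "fraction_by_p", fraction = 0.5)
    expect_length(selectedGenes(frac), 5L)
})

test_that("selection is idempotent", {
    me <- tinyExperiment(nGenes = 50, nPerClass = 5)
    gs <- selectProminent(anovaVolcano(me), "fraction_by_p", fraction = 0.4)
    again <- selectProminent(gs, "fraction_by_p", fraction = 0.4)
    expect_identical(selectedGenes(again), selectedGenes(gs))
})

test_that("strong DE genes are recovered by the default fraction", {
    me <- simulateMicroarray(syntheticConfig(nGenes = 2000, nPerClass = 50,
                                             deFraction = 0.1,
                                             effectSize = 2, seed = 13))
    gs <- selectProminent(anovaVolcano(me), "fraction_by_p")
    expect_length(selectedGenes(gs), round(2000 * 16000 / 33000))
    de <- which(deTruth(me) == 1L)
    expect_gte(mean(de %in% selectedGenes(gs)), 0.95)
})

test_that("under the null the selected set is unenriched in flagged genes", {
    me <- simulateMicroarray(syntheticConfig(nGenes = 2000, nPerClass = 50,
                                             deFraction = 0.1,
                                             effectSize = 0, seed = 17))
    gs <- selectProminent(anovaVolcano(me), "fraction_by_p")
    frac <- 16000 / 33000
    hit <- mean(which(deTruth(me) == 1L) %in% selectedGenes(gs))
    se <- sqrt(frac * (1 - frac) / 200)
    expect_lt(abs(hit - frac), 4 * se)
    # and p-values are uniform
    expect_gt(stats::ks.test(anovaVolcano(me)@pValue, "punif")$p.value, 0.01)
})
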