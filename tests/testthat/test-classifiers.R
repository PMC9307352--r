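test_that("target encoding round-trips through the threshold", {
    expect_equal(encodeTargets(c(1, 0, 1)), c(0.9, 0.1, 0.9))
    expect_equal(encodeTargets(rep(0, 4)), rep(0.1, 4))
    lab <- c(1, 0, 0, 1, 1)
    expect_identical(decodeTargets(encodeTargets(lab)), as.integer(lab))
    expect_error(encodeTargets(c(0, 2)), "binary")
    expect_error(targetEncoding(0.7, 0.3), "gap")
})

test_that("dfaAlpha matches known scaling exponents", {
    withr::with_seed(51, w <- rnorm(4096))
    expect_equal(dfaAlpha(w), 0.5, tolerance = 0.1)
    expect_equal(dfaAlpha(cumsum(w)), 1.5, tolerance = 0.15)
    # a pure linear ramp has an exactly quadratic profile, so polynomial
    # detrending one order above the trend removes it exactly
    ramp <- suppressWarnings(dfaAlpha(seq(0, 1, length.out = 256),
                                      detrendOrder = 2, full = TRUE))
    expect_true(all(ramp$fluctuation < 1e-8))
    expect_warning(a0 <- dfaAlpha(rep(1, 100)), "alpha undefined")
    expect_identical(a0, 0)
    expect_error(dfaAlpha(rnorm(100), boxSizes = c(4, 5, 6)), "4 distinct")
})

test_that("all six classifiers separate two distant classes", {
    sep <- separable1d()
    for (alg in c("GMM", "NLR", "BLDC", "LR", "KNN")) {
        fit <- fitClassifier(sep$x, sep$labels, alg)
        pred <- predict(fit, sep$x)
        expect_identical(pred$label, sep$labels, label = alg)
        expect_true(all(is.finite(pred$score)), label = alg)
    }
    # DFA needs a fluctuation-structured series per sample
    withr::with_seed(52, {
        xx <- t(vapply(1:10, function(i) {
            base <- rnorm(64)
            if (i > 5) cumsum(base) else base
        }, numeric(64)))
    })
    lab <- rep(c(0L, 1L), each = 5)
    fit <- fitClassifier(xx, lab, "DFA")
    expect_identical(predict(fit, xx)$label, lab)
})

test_that("score and label are always consistent at the 0.5 threshold", {
    sep <- separable1d(n = 10, gap = 2, seed = 9)
    withr::with_seed(10, newx <- matrix(rnorm(40, 0, 3), ncol = 1))
    for (alg in c("GMM", "NLR", "BLDC", "LR", "KNN")) {
        fit <- fitClassifier(sep$x, sep$labels, alg)
        pred <- predict(fit, newx)
        expect_identical(pred$label, as.integer(pred$score > 0.5),
                         label = alg)
    }
})

test_that("KNN follows the neighbour-vote contract", {
    sep <- separable1d()
    fit1 <- fitClassifier(sep$x, sep$labels, "KNN", K = 1)
    # a test point identical to a training point takes that point's label
    pred <- predict(fit1, sep$x[c(2, 8), , drop = FALSE])
    expect_identical(pred$label, sep$labels[c(2, 8)])
    expect_error(fitClassifier(sep$x, sep$labels, "KNN", K = 4), "odd")
    # cross-check against the reference implementation
    skip_if_not_installed("class")
    withr::with_seed(53, {
        xtr <- matrix(rnorm(60), 20, 3)
        lab <- rep(c(0L, 1L), 10)
        xte <- matrix(rnorm(30), 10, 3)
    })
    fit3 <- fitClassifier(xtr, lab, "KNN", K = 3)
    ref <- as.integer(as.character(class::knn(xtr, xte, factor(lab), k = 3)))
    expect_identical(predict(fit3, xte)$label, ref)
})

test_that("BLDC approaches the exact solution on noise-free targets", {
    withr::with_seed(54, x <- matrix(rnorm(40), 20, 2))
    w <- c(0.3, -0.2)
    y <- as.vector(x %*% w) + 0.5
    fit <- ovaclass:::fitBldc(x, y)
    expect_equal(fit$w, c(0.5, w), tolerance = 1e-3)
})

test_that("LR equals the normal-equations / pseudo-inverse solution", {
    withr::with_seed(55, {
        x <- matrix(rnorm(30), 10, 3)
        y <- rnorm(10)
    })
    fit <- ovaclass:::fitLr(x, y)
    expect_equal(fit$w,
                 unname(stats::coef(stats::lm(y ~ x))), tolerance = 1e-9)
    # wide case: minimum-norm solution still interpolates
    withr::with_seed(56, {
        xw <- matrix(rnorm(5 * 12), 5, 12)
        yw <- rnorm(5)
    })
    fw <- ovaclass:::fitLr(xw, yw)
    expect_equal(as.vector(cbind(1, xw) %*% fw$w), yw, tolerance = 1e-9)
})

test_that("NLR matches a reference nonlinear least-squares fit", {
    withr::with_seed(57, {
        u <- seq(-2, 2, length.out = 40)
        t <- 0.1 + 0.8 * stats::plogis(0.7 + 1.9 * u) + rnorm(40, 0, 0.01)
    })
    x <- matrix(u, ncol = 1)
    enc <- targetEncoding()
    fit <- ovaclass:::fitNlr(x, t, enc)
    ref <- stats::nls(t ~ 0.1 + 0.8 * plogis(a + b * us),
                      data = list(t = t, us = (u - mean(u)) / sd(u)),
                      start = list(a = 0, b = 2))
    expect_equal(c(fit$a, fit$b), unname(stats::coef(ref)),
                 tolerance = 1e-4)
})

test_that("training-order permutations leave predictions unchanged", {
    withr::with_seed(58, {
        x <- matrix(rnorm(60), 20, 3)
        lab <- rep(c(0L, 1L), each = 10)
        xte <- matrix(rnorm(15), 5, 3)
        perm <- sample(20)
    })
    for (alg in c("KNN", "LR", "BLDC", "GMM", "NLR")) {
        p1 <- predict(fitClassifier(x, lab, alg), xte)
        p2 <- predict(fitClassifier(x[perm, , drop = FALSE], lab[perm],
                                    alg), xte)
        expect_equal(p1$score, p2$score, tolerance = 1e-8, label = alg)
    }
})

test_that("GMM posterior matches the closed-form Gaussian per class", {
    withr::with_seed(59, {
        x <- matrix(rnorm(40, rep(c(0, 3), each = 10)), 20, 2)
        lab <- rep(c(0L, 1L), each = 10)
        xte <- matrix(rnorm(10), 5, 2)
    })
    fit <- fitClassifier(x, lab, "GMM")
    s <- predict(fit, xte)$score
    ll <- function(xm, m) rowSums(vapply(1:2, function(j)
        stats::dnorm(xm[, j], mean(m[, j]),
                     sqrt(mean((m[, j] - mean(m[, j]))^2)), log = TRUE),
        numeric(nrow(xm))))
    lc <- ll(xte, x[lab == 1, ]) + log(0.5)
    ln <- ll(xte, x[lab == 0, ]) + log(0.5)
    post <- 1 / (1 + exp(ln - lc))
    expect_equal(s, 0.1 + 0.8 * post, tolerance = 1e-8)
})

test_that("models serialize to JSON for predict-only reuse", {
    sep <- separable1d()
    fit <- fitClassifier(sep$x, sep$labels, "LR")
    path <- withr::local_tempfile(fileext = ".json")
    exportModel(fit, path)
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_identical(back$algorithm, "LR")
    expect_equal(back$params$w, fit@params$w, tolerance = 1e-12)
})
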