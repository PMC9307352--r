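# small in-code fixtures shared across test files

tinyExperiment <- function(nGenes = 40, nPerClass = 5, effectSize = 2,
                           seed = 42, ...) {
    simulateMicroarray(syntheticConfig(nGenes = nGenes,
                                       nPerClass = nPerClass,
                                       effectSize = effectSize,
                                       seed = seed, ...))
}

# two well-separated 1-D classes for classifier sanity checks
separable1d <- function(n = 5, gap = 10, seed = 7) {
    withr::with_seed(seed, list(
        x = matrix(c(rnorm(n, -gap), rnorm(n, gap)), ncol = 1),
        labels = rep(c(0L, 1L), each = n)))
}

# naive O(n^2) distance-correlation oracle, written index-wise so it shares
# no code path with the package implementation
dcorNaive <- function(x, y) {
    n <- length(x)
    a <- abs(outer(x, x, "-"))
    b <- abs(outer(y, y, "-"))
    A <- matrix(0, n, n); B <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
        B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
    }
    dcov <- sqrt(max(mean(A * B), 0))
    dvx <- sqrt(mean(A * A)); dvy <- sqrt(mean(B * B))
    if (dvx == 0 || dvy == 0) return(0)
    dcov / sqrt(dvx * dvy)
}
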