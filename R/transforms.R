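# Transform-based feature extraction. Each sample's selected-gene vector
# (ascending original gene order) is treated as a discrete signal; the
# default output dimension preserves the 3300/16000 reduction ratio of the
# full-scale pipeline at any input length.

# analytic-signal magnitude envelope via the frequency-domain Hilbert
# multiplier (1 at DC/Nyquist, 2 on positive frequencies, 0 on negative)
analyticEnvelope <- function(x) {
    n <- length(x)
    h <- numeric(n)
    if (n %% 2 == 0) {
        h[c(1, n / 2 + 1)] <- 1
        h[2:(n / 2)] <- 2
    } else {
        h[1] <- 1
        if (n > 1) h[2:((n + 1) / 2)] <- 2
    }
    Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# orthonormal DCT-II via the even/odd FFT reordering
dctII <- function(x) {
    n <- length(x)
    if (n == 1L) return(x)
    v <- x[c(seq(1, n, by = 2), rev(seq(2, n, by = 2)))]
    V <- stats::fft(v)
    k <- 0:(n - 1)
    coeff <- Re(V * exp(-1i * pi * k / (2 * n)))
    coeff * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

defaultTransformDim <- function(g) max(1L, round(g * 3300 / 16000))

transformCheck <- function(m, nFeatures) {
    m <- as.matrix(m)
    if (nFeatures < 1 || nFeatures > nrow(m))
        stop("nFeatures must satisfy 1 <= nFeatures <= number of genes (",
             nrow(m), ")")
    m
}

featureSetFrom <- function(feats, method, nFeatures, sampleIds) {
    dimnames(feats) <- list(sampleIds,
                            paste0(method, seq_len(nFeatures)))
    new("FeatureSet", values = feats, method = method,
        provenance = list(nFeatures = nFeatures))
}

#' Hilbert-envelope feature extraction
#'
#' Per sample, computes the analytic signal of the ordered gene vector via
#' the discrete Hilbert transform and keeps the magnitude envelope,
#' uniformly decimated to \code{nFeatures} points.
#'
#' @param m numeric selected-gene matrix, genes x samples.
#' @param nFeatures output dimension; default preserves the 3300/16000
#'   reduction ratio.
#' @return A [FeatureSet-class] with method "HILBERT".
#' @export
hilbertFeatures <- function(m, nFeatures = NULL) {
    m <- as.matrix(m)
    g <- nrow(m)
    if (is.null(nFeatures)) nFeatures <- defaultTransformDim(g)
    m <- transformCheck(m, nFeatures)
    idx <- ceiling(seq_len(nFeatures) * g / nFeatures)
    feats <- t(apply(m, 2, function(x) analyticEnvelope(x)[idx]))
    if (nFeatures == 1L) feats <- matrix(feats, ncol = 1)
    featureSetFrom(feats, "HILBERT", nFeatures, colnames(m))
}

#' DCT-II feature extraction
#'
#' Per sample, applies the orthonormal DCT-II to the ordered gene vector and
#' keeps the first \code{nFeatures} (lowest-frequency) coefficients, relying
#' on the transform's energy compaction.
#'
#' @inheritParams hilbertFeatures
#' @return A [FeatureSet-class] with method "DCT".
#' @export
dctFeatures <- function(m, nFeatures = NULL) {
    m <- as.matrix(m)
    if (is.null(nFeatures)) nFeatures <- defaultTransformDim(nrow(m))
    m <- transformCheck(m, nFeatures)
    feats <- t(apply(m, 2, function(x) dctII(x)[seq_len(nFeatures)]))
    if (nFeatures == 1L) feats <- matrix(feats, ncol = 1)
    featureSetFrom(feats, "DCT", nFeatures, colnames(m))
}

#' FFT-magnitude feature extraction
#'
#' Per sample, computes the discrete Fourier transform of the ordered gene
#' vector and keeps the magnitudes of the first \code{nFeatures}
#' non-negative-frequency coefficients.
#'
#' @inheritParams hilbertFeatures
#' @return A [FeatureSet-class] with method "FFT".
#' @export
fftFeatures <- function(m, nFeatures = NULL) {
    m <- as.matrix(m)
    if (is.null(nFeatures)) nFeatures <- defaultTransformDim(nrow(m))
    m <- transformCheck(m, nFeatures)
    ft <- stats::mvfft(m)
    feats <- t(Mod(ft[seq_len(nFeatures), , drop = FALSE]))
    featureSetFrom(feats, "FFT", nFeatures, colnames(m))
}
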