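#' Per-class statistical summary of a feature set
#'
#' For each class, pools all feature values of that class's samples and
#' reports mean, standard deviation (n-1), variance, Fisher-Pearson
#' skewness, non-excess Pearson kurtosis (Gaussian -> 3), and sample
#' entropy (embedding dimension m = 2, tolerance r = 0.2 x the series SD,
#' computed per sample on its ordered feature vector and averaged over the
#' class). Two cross-class scalars are attached to both rows:
#' \code{pearson}, the Pearson correlation between the two classes' mean
#' feature vectors, and \code{t_test}, the p-value of a two-sample t-test
#' between the classes' per-sample feature means.
#'
#' A constant per-sample series has sample entropy 0 by convention (with a
#' warning).
#'
#' @param f a [FeatureSet-class].
#' @param labels binary class labels, one per sample (row of \code{f}).
#' @return data.frame with rows "cancer" and "normal" and columns mean,
#'   std_dev, variance, skewness, kurtosis, pearson, t_test,
#'   sample_entropy.
#' @export
featureStatistics <- function(f, labels) {
    v <- featureValues(f)
    if (length(labels) != nrow(v))
        stop("length(labels) must equal the number of samples")
    if (length(unique(labels)) < 2L) stop("both classes must be present")
    perClass <- function(cl) {
        m <- v[labels == cl, , drop = FALSE]
        pooled <- as.vector(m)
        ent <- mean(vapply(seq_len(nrow(m)), function(i)
            sampleEntropy(m[i, ]), numeric(1)))
        c(mean = mean(pooled),
          std_dev = stats::sd(pooled),
          variance = stats::var(pooled),
          skewness = e1071::skewness(pooled, type = 1),
          kurtosis = e1071::kurtosis(pooled, type = 1) + 3,
          sample_entropy = ent)
    }
    s1 <- perClass(1)
    s0 <- perClass(0)
    mean1 <- colMeans(v[labels == 1, , drop = FALSE])
    mean0 <- colMeans(v[labels == 0, , drop = FALSE])
    pearson <- if (stats::sd(mean1) == 0 || stats::sd(mean0) == 0) NA_real_
        else stats::cor(mean1, mean0)
    tp <- tryCatch(
        stats::t.test(rowMeans(v[labels == 1, , drop = FALSE]),
                      rowMeans(v[labels == 0, , drop = FALSE]))$p.value,
        error = function(e) NA_real_)   # degenerate (constant) input
    out <- rbind(cancer = s1, normal = s0)
    data.frame(out[, c("mean", "std_dev", "variance", "skewness", "kurtosis")],
               pearson = pearson, t_test = tp,
               sample_entropy = out[, "sample_entropy"])
}

# sample entropy with m = 2, r = 0.2 * sd; constant or too-short series -> 0
# (warning); an undefined 0/0 match ratio is also mapped to 0
sampleEntropy <- function(x, edim = 2) {
    s <- stats::sd(x)
    if (s == 0 || length(x) < 5) {
        warning("constant or too-short series: sample entropy defined as 0")
        return(0)
    }
    e <- pracma::sample_entropy(x, edim = edim, r = 0.2 * s)
    if (is.nan(e)) 0 else e
}
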