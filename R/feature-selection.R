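#' Correlation distance between two vectors
#'
#' Two variants of the "distance = 1 - correlation" relevance measure:
#' \describe{
#'   \item{\code{pearson_distance}}{\eqn{1 - |r(x, y)|} with \eqn{r} the
#'     Pearson correlation; the absolute value makes anti-correlated
#'     variables count as related. Lies in [0, 1]. If \code{x} is constant
#'     the distance is 1 by convention.}
#'   \item{\code{distance_correlation}}{\eqn{1 - dCor(x, y)} where dCor is
#'     the Szekely distance correlation
#'     \eqn{dCov(X,Y)/\sqrt{dVar(X)\,dVar(Y)}} computed from
#'     double-centered pairwise distance matrices; captures nonlinear
#'     association.}
#' }
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method "pearson_distance" (default) or "distance_correlation".
#' @return scalar distance; 0 means perfectly associated.
#' @examples
#' correlationDistance(1:10, (1:10)^2)
#' correlationDistance(1:10, (1:10)^2, "distance_correlation")
#' @export
correlationDistance <- function(x, y, method = c("pearson_distance",
                                                 "distance_correlation")) {
    method <- match.arg(method)
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("vectors must have length >= 3")
    if (method == "pearson_distance") {
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(1)
        1 - abs(stats::cor(x, y))
    } else {
        1 - distanceCorrelation(x, y)
    }
}

# Szekely distance correlation via double-centered distance matrices
distanceCorrelation <- function(x, y) {
    center <- function(v) {
        d <- as.matrix(stats::dist(v))
        d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
    }
    A <- center(x)
    B <- center(y)
    dcov2 <- mean(A * B)
    dvarx <- mean(A * A)
    dvary <- mean(B * B)
    if (dvarx <= 0 || dvary <= 0) return(0)
    sqrt(max(dcov2, 0)) / sqrt(sqrt(dvarx * dvary))
}

#' Select features by correlation distance to the class label
#'
#' Computes, on the training samples only, the correlation distance between
#' every feature column and the class-label vector, and keeps the \code{k}
#' features with the smallest distance (most label-associated). Ties are
#' broken by lower feature index. The full-scale pipeline keeps 45 features.
#'
#' @param f a [FeatureSet-class] or a samples x features matrix.
#' @param labels binary labels for the rows used.
#' @param k number of features to keep (default 45).
#' @param method distance variant, see [correlationDistance()].
#' @param trainIdx row indices to compute distances on (default all rows).
#' @return list of class \code{"selectedFeatureSet"}: \code{keptIdx}
#'   (ordered by ascending distance then index), \code{distances} (per
#'   feature), \code{method}.
#' @export
selectByCorrelationDistance <- function(f, labels, k = 45,
                                        method = c("pearson_distance",
                                                   "distance_correlation"),
                                        trainIdx = NULL) {
    method <- match.arg(method)
    v <- if (is(f, "FeatureSet")) featureValues(f) else as.matrix(f)
    if (is.null(trainIdx)) trainIdx <- seq_len(nrow(v))
    if (k > ncol(v))
        stop("k = ", k, " exceeds the number of features (", ncol(v), ")")
    vt <- v[trainIdx, , drop = FALSE]
    yt <- as.numeric(labels[trainIdx])
    distances <- vapply(seq_len(ncol(vt)), function(j)
        correlationDistance(vt[, j], yt, method), numeric(1))
    ord <- order(distances, seq_along(distances))
    structure(list(keptIdx = ord[seq_len(k)], distances = distances,
                   method = method),
              class = "selectedFeatureSet")
}
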