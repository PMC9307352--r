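#' Fit a fuzzy C-means model
#'
#' Alternating-optimization fuzzy C-means on a set of items (rows of
#' \code{x}). Memberships follow the standard update
#' \eqn{u_{mc} \propto (1/\|k_m-\mu_c\|^2)^{1/(y-1)}} normalized over
#' clusters, centers are the membership^y-weighted item means, and the
#' objective \eqn{\sum_c \sum_m u_{mc}^y \|k_m-\mu_c\|^2} is non-increasing
#' across iterations. Iteration stops when the largest center shift falls
#' below \code{tol} or after \code{maxIter} sweeps. An item exactly equal to
#' a center takes full membership in that cluster (standard singularity
#' rule).
#'
#' Initial centers are items taken at evenly spaced quantile ranks of the
#' item ordering by row mean; \code{seed} only matters when duplicated
#' initial centers must be jittered apart.
#'
#' @param x numeric matrix (items x dims) or vector of 1-D items.
#' @param C number of clusters (1 <= C <= number of items).
#' @param fuzzifier membership exponent y > 1 (default 2).
#' @param tol convergence tolerance on center movement (default 1e-5).
#' @param maxIter maximum sweeps (default 300).
#' @param seed integer seed (default 1).
#' @return list of class \code{"fcmModel"}: \code{centers} (C x dims),
#'   \code{memberships} (items x C, rows sum to 1), \code{objective}
#'   (per-iteration trace), \code{fuzzifier}, \code{iterations}.
#' @examples
#' fit <- fcmFit(c(0, 0, 0, 10, 10, 10), C = 2)
#' sort(fit$centers[, 1])
#' @export
fcmFit <- function(x, C, fuzzifier = 2, tol = 1e-5, maxIter = 300, seed = 1) {
    if (is.vector(x)) x <- matrix(x, ncol = 1)
    m <- nrow(x)
    if (C < 1 || C > m) stop("C must satisfy 1 <= C <= number of items (", m, ")")
    if (fuzzifier <= 1) stop("fuzzifier must be > 1")
    ord <- order(rowMeans(x), seq_len(m))
    pick <- ord[pmin(m, pmax(1, round((seq_len(C) - 0.5) / C * m + 0.5)))]
    centers <- x[pick, , drop = FALSE]
    if (C > 1 && anyDuplicated(centers)) {
        centers <- withr::with_seed(seed, centers +
            matrix(stats::rnorm(length(centers), 0, 1e-8 + 1e-8 * stats::sd(x)),
                   nrow(centers)))
    }
    xsq <- rowSums(x^2)
    expo <- 1 / (fuzzifier - 1)
    objective <- numeric(0)
    u <- NULL
    for (it in seq_len(maxIter)) {
        d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * x %*% t(centers)
        d2[d2 < 0] <- 0
        u <- (1 / pmax(d2, .Machine$double.xmin))^expo
        u <- u / rowSums(u)
        zero <- which(d2 <= .Machine$double.eps * pmax(1, xsq), arr.ind = TRUE)
        if (nrow(zero)) {
            rows <- unique(zero[, 1])
            u[rows, ] <- 0
            first <- zero[!duplicated(zero[, 1]), , drop = FALSE]
            u[first] <- 1
        }
        uy <- u^fuzzifier
        objective <- c(objective, sum(uy * d2))
        newCenters <- t(uy) %*% x / pmax(colSums(uy), .Machine$double.xmin)
        shift <- max(abs(newCenters - centers))
        centers <- newCenters
        if (shift < tol) break
    }
    structure(list(centers = centers, memberships = u,
                   objective = objective, fuzzifier = fuzzifier,
                   tol = tol, iterations = length(objective), seed = seed),
              class = "fcmModel")
}

#' Fuzzy C-means feature extraction
#'
#' Clusters the genes of a selected-gene matrix into \code{C} groups by
#' fuzzy C-means on their expression profiles across the \emph{training}
#' samples, then summarizes every sample (training and test alike) as the
#' membership-weighted average of its expression over each cluster:
#' \eqn{f_{sc} = \sum_g u_{gc} x_{gs} / \sum_g u_{gc}}. At the full study
#' scale this reduces 16,000 genes to 660 features per sample; the default
#' \code{C} preserves that 660/16000 ratio at any input size.
#'
#' @param m numeric selected-gene matrix, genes x samples.
#' @param trainIdx column indices of the training samples the clustering may
#'   see (default all).
#' @param C cluster count; default \code{max(1, round(nGenes * 660/16000))}.
#' @param fuzzifier,tol,maxIter,seed passed to [fcmFit()].
#' @return A [FeatureSet-class] with method "FCM"; provenance records C,
#'   the FCM parameters and the training sample ids.
#' @export
fcmFeatures <- function(m, trainIdx = seq_len(ncol(m)), C = NULL,
                        fuzzifier = 2, tol = 1e-5, maxIter = 300, seed = 1) {
    m <- as.matrix(m)
    g <- nrow(m)
    if (is.null(C)) C <- max(1L, round(g * 660 / 16000))
    if (C > g) stop("C = ", C, " exceeds the number of genes (", g, ")")
    fit <- fcmFit(m[, trainIdx, drop = FALSE], C = C, fuzzifier = fuzzifier,
                  tol = tol, maxIter = maxIter, seed = seed)
    u <- fit$memberships
    feats <- t(m) %*% u / rep(colSums(u), each = ncol(m))
    dimnames(feats) <- list(colnames(m), paste0("FCM", seq_len(C)))
    new("FeatureSet", values = feats, method = "FCM",
        provenance = list(C = C, fuzzifier = fuzzifier, tol = tol,
                          maxIter = maxIter, seed = seed,
                          trainSamples = if (!is.null(colnames(m)))
                              colnames(m)[trainIdx] else trainIdx,
                          iterations = fit$iterations))
}
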