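#' Class-target encoding
#'
#' All six classifiers are trained against regression targets rather than
#' 0/1 labels: cancer samples map to \code{tCancer} = 0.9, normal samples
#' to \code{tNormal} = 0.1, and predictions are thresholded at 0.5. The
#' target gap must satisfy \code{tCancer - tNormal >= 0.5}.
#'
#' @param tCancer cancer target (default 0.9).
#' @param tNormal normal target (default 0.1).
#' @param threshold decision threshold (default 0.5).
#' @return list with the three components, validated.
#' @export
targetEncoding <- function(tCancer = 0.9, tNormal = 0.1, threshold = 0.5) {
    if (tCancer - tNormal < 0.5)
        stop("target gap tCancer - tNormal must be >= 0.5")
    if (threshold <= tNormal || threshold >= tCancer)
        stop("threshold must lie strictly between tNormal and tCancer")
    list(tCancer = tCancer, tNormal = tNormal, threshold = threshold)
}

#' Encode binary labels as regression targets
#'
#' @param labels binary vector (1 = cancer, 0 = normal).
#' @param encoding a [targetEncoding()] list.
#' @return numeric vector of targets (0.9 / 0.1 by default).
#' @examples
#' encodeTargets(c(1, 0, 1))
#' @export
encodeTargets <- function(labels, encoding = targetEncoding()) {
    if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
    ifelse(labels == 1, encoding$tCancer, encoding$tNormal)
}

#' Decode scores back to binary labels
#'
#' @param scores numeric scores.
#' @param encoding a [targetEncoding()] list.
#' @return integer labels; a score strictly above the threshold is cancer
#'   (ties go to normal).
#' @export
decodeTargets <- function(scores, encoding = targetEncoding()) {
    as.integer(scores > encoding$threshold)
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Computes the DFA exponent of a series: the profile is the cumulative sum
#' of the mean-centered series; for each box size the profile is split into
#' non-overlapping boxes, a polynomial of order \code{detrendOrder} is
#' fitted per box, and the root-mean-square fluctuation of the residuals is
#' taken; alpha is the least-squares slope of log fluctuation versus log
#' box size. White noise gives alpha about 0.5, its cumulative sum about
#' 1.5. A (near-)constant series, whose fluctuations vanish, returns 0 with
#' a warning.
#'
#' @param series numeric vector, length >= 4 x the smallest box size.
#' @param boxSizes integer box sizes (>= 4, at least 4 distinct). Default:
#'   8 log-spaced sizes from 4 to length/4.
#' @param detrendOrder polynomial detrending order (default 1).
#' @param full if TRUE return a list with alpha, boxSizes and the
#'   fluctuation function instead of just alpha.
#' @return scalar alpha (or a list when \code{full = TRUE}).
#' @examples
#' dfaAlpha(cumsum(rnorm(512)))
#' @export
dfaAlpha <- function(series, boxSizes = NULL, detrendOrder = 1,
                     full = FALSE) {
    n <- length(series)
    if (is.null(boxSizes)) {
        smax <- floor(n / 4)
        if (smax < 4) stop("series too short for DFA (need length >= 16)")
        boxSizes <- unique(round(exp(seq(log(4), log(smax), length.out = 8))))
    }
    boxSizes <- sort(unique(as.integer(boxSizes)))
    if (any(boxSizes < 4) || length(boxSizes) < 4)
        stop("need at least 4 distinct box sizes, all >= 4")
    if (n < 4 * min(boxSizes)) stop("series length must be >= 4 x min box size")
    profile <- cumsum(series - mean(series))
    G <- vapply(boxSizes, function(s) {
        nb <- floor(n / s)
        y <- matrix(profile[seq_len(nb * s)], nrow = s)
        t <- seq_len(s)
        X <- stats::poly(t, degree = detrendOrder, raw = TRUE)
        qrD <- qr(cbind(1, X))
        res <- qr.resid(qrD, y)
        sqrt(mean(res^2))
    }, numeric(1))
    ok <- G > 1e-12
    if (sum(ok) < 2) {
        warning("fluctuations vanish at (almost) all scales; alpha undefined, returning 0")
        alpha <- 0
    } else {
        alpha <- unname(stats::coef(stats::lm(log(G[ok]) ~ log(boxSizes[ok])))[2])
    }
    if (full) list(alpha = alpha, boxSizes = boxSizes, fluctuation = G)
    else alpha
}

#' Fit one of the six classifiers
#'
#' Trains a classifier of the given algorithm on a samples x features
#' matrix against the 0.9/0.1 target encoding. All algorithms emit, at
#' prediction time, a continuous score in target units and a binary label
#' (cancer iff score > threshold; ties go to normal).
#'
#' \describe{
#'   \item{GMM}{per-class mixture of \code{Q} diagonal-covariance Gaussians
#'     (default Q = 1) fit by EM with a variance floor; the score is the
#'     posterior probability of cancer mapped onto [tNormal, tCancer].}
#'   \item{DFA}{per-sample [dfaAlpha()] of the feature vector (ascending
#'     feature order); the decision threshold is the midpoint of the class
#'     mean alphas on training data, and the score maps alpha monotonically
#'     onto [tNormal, tCancer] with the cancer class on the high side.}
#'   \item{NLR}{nonlinear regression
#'     \eqn{tN + (tC - tN)/(1 + e^{-(a + b u)})} on the sample-mean feature
#'     \eqn{u}, with (a, b) fit to the encoded targets by Gauss-Newton
#'     (max 200 iterations, tolerance 1e-8).}
#'   \item{BLDC}{Bayesian linear regression of the encoded targets on the
#'     features plus bias, with prior precision alpha and noise precision
#'     beta set by evidence maximization.}
#'   \item{LR}{ordinary least squares on (bias, features), via the
#'     pseudo-inverse so feature counts exceeding the sample count are
#'     handled (minimum-norm solution).}
#'   \item{KNN}{K-nearest neighbours under Euclidean distance; K must be
#'     odd (default 3); the score is the cancer vote fraction mapped onto
#'     [tNormal, tCancer].}
#' }
#'
#' @param x numeric samples x features matrix.
#' @param labels binary training labels (>= 2 samples per class).
#' @param algorithm one of "GMM", "DFA", "NLR", "BLDC", "LR", "KNN".
#' @param encoding a [targetEncoding()] list.
#' @param Q GMM components per class (default 1).
#' @param K KNN neighbour count, odd (default 3).
#' @param boxSizes,detrendOrder DFA parameters (see [dfaAlpha()]).
#' @param lambdaRidge tiny Gauss-Newton ridge for NLR (default 1e-10).
#' @param seed integer seed for the (only) stochastic initializer, the
#'   GMM component split when Q > 1.
#' @return A [ClassifierModel-class]; use [predict()] on new data.
#' @examples
#' x <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1)
#' lab <- rep(c(0, 1), each = 10)
#' fit <- fitClassifier(x, lab, "LR")
#' predict(fit, x)$label
#' @export
fitClassifier <- function(x, labels, algorithm = c("GMM", "DFA", "NLR",
                                                   "BLDC", "LR", "KNN"),
                          encoding = targetEncoding(), Q = 1, K = 3,
                          boxSizes = NULL, detrendOrder = 1,
                          lambdaRidge = 1e-10, seed = 1) {
    algorithm <- match.arg(algorithm)
    x <- as.matrix(x)
    if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
    if (min(table(labels)) < 2) stop("need >= 2 samples per class")
    t <- encodeTargets(labels, encoding)
    params <- switch(algorithm,
        GMM = fitGmm(x, labels, Q, seed),
        DFA = fitDfaClassifier(x, labels, boxSizes, detrendOrder),
        NLR = fitNlr(x, t, encoding, lambdaRidge),
        BLDC = fitBldc(x, t),
        LR = fitLr(x, t),
        KNN = {
            if (K %% 2 == 0) stop("K must be an odd integer")
            list(X = x, labels = as.integer(labels), K = as.integer(K))
        })
    new("ClassifierModel", algorithm = algorithm, params = params,
        encoding = encoding)
}

#' Predict scores and labels from a fitted classifier
#'
#' @param object a [ClassifierModel-class].
#' @param newdata numeric samples x features matrix with the same feature
#'   dimension the model was trained on.
#' @param ... ignored.
#' @return data.frame with columns \code{score} (target-scale, finite) and
#'   \code{label} (1 = cancer iff score > threshold).
#' @export
setMethod("predict", "ClassifierModel", function(object, newdata, ...) {
    x <- as.matrix(newdata)
    e <- object@encoding
    score <- switch(object@algorithm,
        GMM = predictGmm(object@params, x, e),
        DFA = predictDfaClassifier(object@params, x, e),
        NLR = predictNlr(object@params, x, e),
        BLDC = as.vector(cbind(1, x) %*% object@params$w),
        LR = as.vector(cbind(1, x) %*% object@params$w),
        KNN = predictKnn(object@params, x, e))
    data.frame(score = score, label = decodeTargets(score, e))
})

## ---- GMM ----------------------------------------------------------------

# diagonal-covariance Gaussian mixture per class, EM with a variance floor
fitGmm <- function(x, labels, Q = 1, seed = 1) {
    d <- ncol(x)
    floorVar <- pmax(1e-6 * apply(x, 2, stats::var), 1e-12)
    fitOne <- function(xc) {
        n <- nrow(xc)
        if (Q == 1) {
            mu <- matrix(colMeans(xc), 1)
            sig <- matrix(pmax(apply(xc, 2, function(v)
                mean((v - mean(v))^2)), floorVar), 1, byrow = TRUE)
            return(list(weights = 1, mu = mu, sigma2 = sig))
        }
        grp <- withr::with_seed(seed,
            stats::kmeans(xc, centers = min(Q, n - 1), nstart = 3)$cluster)
        mu <- do.call(rbind, lapply(split(seq_len(n), grp), function(i)
            colMeans(xc[i, , drop = FALSE])))
        sig <- matrix(rep(pmax(apply(xc, 2, stats::var), floorVar),
                          each = nrow(mu)), nrow(mu))
        w <- as.vector(table(grp)) / n
        for (it in seq_len(100)) {
            ll <- vapply(seq_along(w), function(q)
                log(w[q]) + gmmLogDens(xc, mu[q, ], sig[q, ]), numeric(n))
            M <- apply(ll, 1, max)
            r <- exp(ll - M)
            r <- r / rowSums(r)
            wNew <- colMeans(r)
            muNew <- t(vapply(seq_along(w), function(q)
                colSums(r[, q] * xc) / sum(r[, q]), numeric(d)))
            sigNew <- t(vapply(seq_along(w), function(q) {
                v <- colSums(r[, q] * sweep(xc, 2, muNew[q, ])^2) / sum(r[, q])
                pmax(v, floorVar)
            }, numeric(d)))
            delta <- max(abs(muNew - mu), abs(wNew - w))
            w <- wNew; mu <- muNew; sig <- sigNew
            if (delta < 1e-8) break
        }
        list(weights = w, mu = mu, sigma2 = sig)
    }
    if (any(apply(x, 2, stats::var) < .Machine$double.eps))
        warning("degenerate feature variance; variance floor applied")
    list(cancer = fitOne(x[labels == 1, , drop = FALSE]),
         normal = fitOne(x[labels == 0, , drop = FALSE]),
         logPrior = log(c(cancer = mean(labels == 1),
                          normal = mean(labels == 0))),
         Q = Q)
}

gmmLogDens <- function(x, mu, sigma2) {
    # x: n x d, diagonal Gaussian log density
    rowSums(-0.5 * (log(2 * pi * rep(sigma2, each = nrow(x))) +
                    sweep(x, 2, mu)^2 / rep(sigma2, each = nrow(x))))
}

gmmClassLogLik <- function(comp, x) {
    ll <- vapply(seq_along(comp$weights), function(q)
        log(comp$weights[q]) + gmmLogDens(x, comp$mu[q, ], comp$sigma2[q, ]),
        numeric(nrow(x)))
    if (is.vector(ll)) ll <- matrix(ll, nrow = nrow(x))
    M <- apply(ll, 1, max)
    M + log(rowSums(exp(ll - M)))
}

predictGmm <- function(p, x, e) {
    lc <- gmmClassLogLik(p$cancer, x) + p$logPrior[["cancer"]]
    ln <- gmmClassLogLik(p$normal, x) + p$logPrior[["normal"]]
    post <- 1 / (1 + exp(pmin(pmax(ln - lc, -700), 700)))
    e$tNormal + (e$tCancer - e$tNormal) * post
}

## ---- DFA classifier -----------------------------------------------------

fitDfaClassifier <- function(x, labels, boxSizes, detrendOrder) {
    alphas <- apply(x, 1, function(s)
        suppressWarnings(dfaAlpha(s, boxSizes, detrendOrder)))
    mC <- mean(alphas[labels == 1])
    mN <- mean(alphas[labels == 0])
    thr <- (mC + mN) / 2
    gain <- 4 / max(abs(mC - mN), 1e-8)
    list(threshold = thr, orientation = sign(mC - mN), gain = gain,
         meanAlphaCancer = mC, meanAlphaNormal = mN,
         boxSizes = boxSizes, detrendOrder = detrendOrder)
}

predictDfaClassifier <- function(p, x, e) {
    alphas <- apply(x, 1, function(s)
        suppressWarnings(dfaAlpha(s, p$boxSizes, p$detrendOrder)))
    z <- p$orientation * (alphas - p$threshold) * p$gain
    e$tNormal + (e$tCancer - e$tNormal) * stats::plogis(z)
}

## ---- NLR ----------------------------------------------------------------

fitNlr <- function(x, t, e, ridge = 1e-10, maxIter = 200, tol = 1e-8) {
    u <- rowMeans(x)
    ctr <- mean(u)
    scl <- stats::sd(u)
    if (scl == 0) scl <- 1
    us <- (u - ctr) / scl
    span <- e$tCancer - e$tNormal
    b <- 2 * sign(stats::cov(us, t) + .Machine$double.eps)
    a <- 0
    sse <- function(a, b) {
        p <- stats::plogis(a + b * us)
        sum((t - (e$tNormal + span * p))^2)
    }
    cur <- sse(a, b)
    for (it in seq_len(maxIter)) {
        p <- stats::plogis(a + b * us)
        f <- e$tNormal + span * p
        r <- t - f
        g <- span * p * (1 - p)
        J <- cbind(g, g * us)
        H <- crossprod(J) + diag(ridge, 2)
        step <- solve(H, crossprod(J, r))
        lam <- 1
        repeat {
            aNew <- a + lam * step[1]; bNew <- b + lam * step[2]
            if (sse(aNew, bNew) <= cur + 1e-15 || lam < 1e-8) break
            lam <- lam / 2
        }
        moved <- max(abs(c(aNew - a, bNew - b)))
        a <- aNew; b <- bNew; cur <- sse(a, b)
        if (moved < tol) break
    }
    list(a = a, b = b, center = ctr, scale = scl)
}

predictNlr <- function(p, x, e) {
    us <- (rowMeans(x) - p$center) / p$scale
    e$tNormal + (e$tCancer - e$tNormal) * stats::plogis(p$a + p$b * us)
}

## ---- BLDC ---------------------------------------------------------------

# Bayesian linear regression with evidence-maximized hyperparameters,
# iterated on the SVD of the design matrix for numerical stability (works
# for d >= n and in the noise-free beta -> Inf limit)
fitBldc <- function(x, t, maxIter = 100, tol = 1e-6) {
    Phi <- cbind(1, x)
    n <- nrow(Phi)
    sv <- svd(Phi)
    d2 <- sv$d^2
    Ut <- crossprod(sv$u, t)                 # rank-length projections
    alpha <- 1e-3
    beta <- 1 / max(stats::var(t), 1e-8)
    solveW <- function(alpha, beta) {
        coef <- sv$d * beta / (alpha + beta * d2)
        as.vector(sv$v %*% (coef * Ut))
    }
    w <- solveW(alpha, beta)
    for (it in seq_len(maxIter)) {
        gamma <- sum(beta * d2 / (alpha + beta * d2))
        rss <- sum((t - Phi %*% w)^2)
        alphaNew <- gamma / max(sum(w^2), 1e-12)
        betaNew <- if (rss < 1e-12) 1e12 else max(n - gamma, 1e-8) / rss
        done <- abs(alphaNew - alpha) < tol * max(alpha, 1) &&
                abs(betaNew - beta) < tol * max(beta, 1)
        alpha <- max(alphaNew, 1e-10)
        beta <- min(betaNew, 1e12)
        w <- solveW(alpha, beta)
        if (done || beta >= 1e12) break
    }
    list(w = w, alpha = alpha, beta = beta)
}

## ---- LR -----------------------------------------------------------------

# ordinary least squares via the Moore-Penrose pseudo-inverse
fitLr <- function(x, t) {
    Phi <- cbind(1, x)
    list(w = as.vector(MASS::ginv(Phi) %*% t))
}

## ---- KNN ----------------------------------------------------------------

predictKnn <- function(p, x, e) {
    d2 <- outer(rowSums(x^2), rowSums(p$X^2), "+") - 2 * x %*% t(p$X)
    votes <- apply(d2, 1, function(dr) {
        nb <- order(dr)[seq_len(min(p$K, length(dr)))]
        mean(p$labels[nb] == 1L)
    })
    e$tNormal + (e$tCancer - e$tNormal) * votes
}

#' Serialize a classifier model to JSON
#'
#' Writes the algorithm tag, fitted parameters and target encoding so a
#' predict-only run can be reproduced.
#'
#' @param model a [ClassifierModel-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
exportModel <- function(model, path) {
    stopifnot(is(model, "ClassifierModel"))
    jsonlite::write_json(list(algorithm = model@algorithm,
                              params = model@params,
                              encoding = model@encoding),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
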