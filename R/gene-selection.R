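#' Per-gene ANOVA and fold change (volcano statistics)
#'
#' For every gene, computes the one-way ANOVA F statistic and p-value
#' between the two classes, and the log2 fold change
#' \code{log2(mean cancer / mean normal)} on the intensity scale (class
#' means are floored at 1e-9 before the ratio). With two groups the ANOVA F
#' equals the square of the pooled two-sample t statistic. Genes whose two
#' groups are identical and constant (zero within-group variance, equal
#' means) get F = 0 and p = 1 by convention and are flagged in the result's
#' criterion record; zero within-group variance with distinct means gives
#' p = 0.
#'
#' @param x a [MicroarrayExperiment-class] (both classes need >= 2 samples).
#' @return A [GeneSelection-class] with empty \code{selectedIdx}.
#' @examples
#' me <- simulateMicroarray(syntheticConfig(nGenes = 100, nPerClass = 5))
#' gs <- anovaVolcano(me)
#' head(gs@pValue)
#' @export
anovaVolcano <- function(x) {
    stopifnot(is(x, "MicroarrayExperiment"))
    v <- exprsValues(x)
    lab <- classLabels(x)
    n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
    if (n1 < 2L || n0 < 2L)
        stop("each class needs at least 2 samples for per-gene ANOVA")
    m1 <- rowMeans(v[, lab == 1L, drop = FALSE])
    m0 <- rowMeans(v[, lab == 0L, drop = FALSE])
    ss1 <- rowSums((v[, lab == 1L, drop = FALSE] - m1)^2)
    ss0 <- rowSums((v[, lab == 0L, drop = FALSE] - m0)^2)
    n <- n0 + n1
    grand <- (n1 * m1 + n0 * m0) / n
    ssb <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
    ssw <- ss1 + ss0
    f <- (ssb / 1) / (ssw / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
    degenerate <- ssw <= 0 & ssb <= .Machine$double.eps * pmax(1, grand^2)
    f[degenerate] <- 0
    p[degenerate] <- 1
    p[ssw <= 0 & !degenerate] <- 0
    f[ssw <= 0 & !degenerate] <- Inf
    eps <- 1e-9
    lfc <- log2(pmax(m1, eps) / pmax(m0, eps))
    new("GeneSelection", fStat = unname(f), pValue = unname(p),
        log2FoldChange = unname(lfc), selectedIdx = integer(0),
        criterion = list(mode = "none",
                         degenerate = unname(which(degenerate))))
}

#' Select the prominent gene subset
#'
#' Applies one of three selection criteria to per-gene volcano statistics:
#' \describe{
#'   \item{\code{fraction_by_p}}{keep \code{round(fraction * nGenes)} genes
#'     with the smallest p-values. The default fraction 16000/33000 mirrors
#'     the reduction from 33,000 assayed genes to 16,000 prominent genes.}
#'   \item{\code{top_k_by_p}}{keep the \code{k} smallest p-values.}
#'   \item{\code{thresholds}}{volcano-style cut: keep genes with
#'     \code{p < pMax} and \code{|log2FC| > fcMin}.}
#' }
#' p-value ties are broken by larger absolute log2 fold change, then by
#' lower gene index. The returned indices are sorted ascending, so the gene
#' order the transform-based extractors depend on is the original array
#' order. Re-applying the same criterion to an already-selected result is a
#' no-op.
#'
#' @param r a [GeneSelection-class] from [anovaVolcano()].
#' @param mode "fraction_by_p", "top_k_by_p" or "thresholds".
#' @param k number of genes for top_k_by_p.
#' @param fraction fraction of genes for fraction_by_p (default 16/33).
#' @param pMax,fcMin thresholds mode cutoffs.
#' @return The [GeneSelection-class] with \code{selectedIdx} filled.
#' @export
selectProminent <- function(r, mode = c("fraction_by_p", "top_k_by_p",
                                        "thresholds"),
                            k = NULL, fraction = 16000 / 33000,
                            pMax = 0.01, fcMin = 1) {
    stopifnot(is(r, "GeneSelection"))
    mode <- match.arg(mode)
    n <- length(r@pValue)
    keep <- switch(mode,
        top_k_by_p = ,
        fraction_by_p = {
            if (mode == "fraction_by_p") k <- round(fraction * n)
            if (is.null(k)) stop("k is required for top_k_by_p")
            if (k > n) stop("k = ", k, " exceeds the number of genes (", n, ")")
            ord <- order(r@pValue, -abs(r@log2FoldChange), seq_len(n))
            ord[seq_len(k)]
        },
        thresholds = which(r@pValue < pMax & abs(r@log2FoldChange) > fcMin))
    r@selectedIdx <- sort(as.integer(keep))
    r@criterion <- list(mode = mode, k = k, fraction = fraction,
                        pMax = pMax, fcMin = fcMin,
                        degenerate = r@criterion$degenerate)
    validObject(r)
    r
}

#' Subset an expression matrix to the selected genes
#'
#' @param x a [MicroarrayExperiment-class].
#' @param r a [GeneSelection-class] with \code{selectedIdx} filled.
#' @return numeric matrix, selected genes x samples, in ascending original
#'   gene order.
#' @export
prominentMatrix <- function(x, r) {
    stopifnot(is(x, "MicroarrayExperiment"), is(r, "GeneSelection"))
    if (!length(r@selectedIdx)) stop("no genes selected; run selectProminent()")
    exprsValues(x)[r@selectedIdx, , drop = FALSE]
}
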