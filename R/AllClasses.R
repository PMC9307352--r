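#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MicroarrayExperiment: a labeled expression matrix
#'
#' Container for a genes x samples intensity matrix with a binary class
#' label per sample (1 = cancer, 0 = normal). Extends
#' \linkS4class{SummarizedExperiment}; the single assay is named
#' \code{"exprs"}, labels live in \code{colData(x)$label}, and -- for
#' synthetic data only -- the per-gene differential-expression ground truth
#' lives in \code{rowData(x)$de_truth}.
#'
#' @slot .  inherits all slots from SummarizedExperiment
#' @seealso [MicroarrayExperiment()] (constructor), [simulateMicroarray()]
#' @exportClass MicroarrayExperiment
setClass("MicroarrayExperiment", contains = "SummarizedExperiment")

setValidity("MicroarrayExperiment", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v)) msg <- c(msg, "assay 'exprs' must be numeric")
        else if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "assay 'exprs' contains missing or non-finite values")
    }
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData column 'label' is required")
    else {
        lab <- SummarizedExperiment::colData(object)$label
        if (!all(lab %in% c(0L, 1L)))
            msg <- c(msg, "labels must be binary (0 = normal, 1 = cancer)")
        else if (length(unique(lab)) < 2L)
            msg <- c(msg, "both classes must be present")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MicroarrayExperiment
#'
#' @param values numeric genes x samples matrix of expression intensities.
#' @param geneIds character vector of gene identifiers (default G1..Gn).
#' @param sampleIds character vector of sample identifiers (default S1..Sm).
#' @param labels binary vector, one per sample; 1 = cancer, 0 = normal.
#' @param deTruth optional binary vector, one per gene; 1 marks a gene
#'   simulated as differentially expressed. Only meaningful for synthetic
#'   data.
#' @return A [MicroarrayExperiment-class] object.
#' @examples
#' m <- matrix(rexp(60, 1 / 50), nrow = 10)
#' me <- MicroarrayExperiment(m, labels = rep(c(0, 1), each = 3))
#' classLabels(me)
#' @export
MicroarrayExperiment <- function(values, geneIds = NULL, sampleIds = NULL,
                                 labels, deTruth = NULL) {
    values <- as.matrix(values)
    if (is.null(geneIds)) geneIds <- paste0("G", seq_len(nrow(values)))
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(values)))
    if (length(labels) != ncol(values))
        stop("length(labels) must equal the number of samples")
    labels <- as.integer(labels)
    dimnames(values) <- list(geneIds, sampleIds)
    rd <- S4Vectors::DataFrame(row.names = geneIds)
    if (!is.null(deTruth)) {
        if (length(deTruth) != nrow(values))
            stop("length(deTruth) must equal the number of genes")
        rd$de_truth <- as.integer(deTruth)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(label = labels, row.names = sampleIds),
        rowData = rd)
    new("MicroarrayExperiment", se)
}

#' Per-gene ANOVA / volcano statistics with an optional selected subset
#'
#' Holds the per-gene one-way ANOVA F statistic, p-value and log2 fold
#' change (cancer over normal), plus the indices of the genes retained by
#' [selectProminent()] and a record of the criterion used.
#'
#' @slot fStat numeric, per-gene ANOVA F.
#' @slot pValue numeric in [0, 1], per-gene p.
#' @slot log2FoldChange numeric, per-gene log2(mean cancer / mean normal).
#' @slot selectedIdx integer, sorted unique gene indices (empty until
#'   selection is applied).
#' @slot criterion list describing the selection mode and parameters.
#' @exportClass GeneSelection
setClass("GeneSelection",
    representation(fStat = "numeric", pValue = "numeric",
                   log2FoldChange = "numeric", selectedIdx = "integer",
                   criterion = "list"))

setValidity("GeneSelection", function(object) {
    n <- length(object@fStat)
    msg <- NULL
    if (length(object@pValue) != n || length(object@log2FoldChange) != n)
        msg <- c(msg, "fStat, pValue and log2FoldChange must share length")
    if (any(object@pValue < 0 | object@pValue > 1, na.rm = TRUE))
        msg <- c(msg, "pValue must lie in [0, 1]")
    idx <- object@selectedIdx
    if (length(idx)) {
        if (is.unsorted(idx, strictly = TRUE))
            msg <- c(msg, "selectedIdx must be sorted and unique")
        if (min(idx) < 1L || max(idx) > n)
            msg <- c(msg, "selectedIdx out of range")
    }
    if (is.null(msg)) TRUE else msg
})

#' A samples x features matrix from one extraction method
#'
#' @slot values numeric samples x features matrix (no NA/Inf).
#' @slot method one of "FCM", "SDA", "HILBERT", "FFT", "DCT".
#' @slot provenance list of fit parameters; for the trained extractors
#'   (FCM, SDA) it records the training-sample ids so train/test hygiene is
#'   auditable.
#' @exportClass FeatureSet
setClass("FeatureSet",
    representation(values = "matrix", method = "character",
                   provenance = "list"))

setValidity("FeatureSet", function(object) {
    msg <- NULL
    if (!object@method %in% c("FCM", "SDA", "HILBERT", "FFT", "DCT"))
        msg <- c(msg, "method must be one of FCM, SDA, HILBERT, FFT, DCT")
    if (anyNA(object@values) || any(!is.finite(object@values)))
        msg <- c(msg, "feature values must be finite")
    if (is.null(msg)) TRUE else msg
})

#' A fitted classifier with its 0.9/0.1 target encoding
#'
#' Common container for the six classifier variants. \code{params} holds the
#' algorithm-specific fitted quantities; \code{encoding} the class-target
#' encoding (cancer target, normal target, decision threshold).
#'
#' @slot algorithm one of "GMM", "DFA", "NLR", "BLDC", "LR", "KNN".
#' @slot params list of fitted parameters.
#' @slot encoding list with tCancer, tNormal, threshold.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
    representation(algorithm = "character", params = "list",
                   encoding = "list"))

setValidity("ClassifierModel", function(object) {
    msg <- NULL
    if (!object@algorithm %in% c("GMM", "DFA", "NLR", "BLDC", "LR", "KNN"))
        msg <- c(msg, "unknown algorithm tag")
    e <- object@encoding
    if (!all(c("tCancer", "tNormal", "threshold") %in% names(e)))
        msg <- c(msg, "encoding must name tCancer, tNormal, threshold")
    else if (e$tCancer - e$tNormal < 0.5 - 1e-12 ||
             e$threshold <= e$tNormal || e$threshold >= e$tCancer)
        msg <- c(msg, "encoding must satisfy tCancer - tNormal >= 0.5 and tNormal < threshold < tCancer")
    if (is.null(msg)) TRUE else msg
})

#' Confusion-matrix counts
#'
#' @slot tp,tn,fp,fn non-negative integer counts; their total is positive.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
    representation(tp = "numeric", tn = "numeric", fp = "numeric",
                   fn = "numeric"))

setValidity("ConfusionMatrix", function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0) || any(v != round(v))) return("counts must be non-negative integers")
    if (sum(v) <= 0) return("total count must be positive")
    TRUE
})

#' Cross-validation result for one pipeline cell
#'
#' @slot foldConfusions list of per-fold [ConfusionMatrix-class] objects.
#' @slot pooled pooled [ConfusionMatrix-class] (sum over folds).
#' @slot metrics named numeric: the nine-metric report derived from the
#'   pooled confusion plus the mean per-fold score MSE.
#' @slot folds list of test-sample index vectors, one per fold.
#' @slot seed integer seed that generated the fold assignment.
#' @slot config list describing the pipeline cell (feature method,
#'   classifier, selection setting, parameters).
#' @exportClass CrossValidationResult
setClass("CrossValidationResult",
    representation(foldConfusions = "list", pooled = "ConfusionMatrix",
                   metrics = "numeric", folds = "list", seed = "integer",
                   config = "list"))

setValidity("CrossValidationResult", function(object) {
    msg <- NULL
    tot <- Reduce(`+`, lapply(object@foldConfusions, function(cm)
        c(cm@tp, cm@tn, cm@fp, cm@fn)), accumulate = FALSE)
    if (!is.null(tot) &&
        !isTRUE(all.equal(tot, c(object@pooled@tp, object@pooled@tn,
                                 object@pooled@fp, object@pooled@fn))))
        msg <- c(msg, "pooled confusion must equal the sum of fold confusions")
    idx <- sort(unlist(object@folds))
    if (length(idx) && any(duplicated(idx)))
        msg <- c(msg, "fold test sets must be disjoint")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MicroarrayExperiment", function(object) {
    lab <- SummarizedExperiment::colData(object)$label
    cat("MicroarrayExperiment:", nrow(object), "genes x", ncol(object),
        "samples (", sum(lab == 1L), "cancer /", sum(lab == 0L), "normal )\n")
    if ("de_truth" %in% colnames(SummarizedExperiment::rowData(object)))
        cat("  synthetic DE truth:",
            sum(SummarizedExperiment::rowData(object)$de_truth), "genes flagged\n")
    callNextMethod()
})

setMethod("show", "GeneSelection", function(object) {
    cat("GeneSelection over", length(object@fStat), "genes;",
        length(object@selectedIdx), "selected")
    if (length(object@criterion))
        cat(" (mode =", object@criterion$mode, ")")
    cat("\n")
})

setMethod("show", "FeatureSet", function(object) {
    cat("FeatureSet:", object@method, "-", nrow(object@values), "samples x",
        ncol(object@values), "features\n")
})

setMethod("show", "ClassifierModel", function(object) {
    cat("ClassifierModel:", object@algorithm,
        sprintf("(targets %.1f/%.1f, threshold %.1f)\n",
                object@encoding$tCancer, object@encoding$tNormal,
                object@encoding$threshold))
})

setMethod("show", "ConfusionMatrix", function(object) {
    cat(sprintf("ConfusionMatrix: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
                object@tp, object@tn, object@fp, object@fn,
                object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "CrossValidationResult", function(object) {
    cfg <- object@config
    cat("CrossValidationResult:",
        if (!is.null(cfg$featureMethod)) cfg$featureMethod else "?", "+",
        if (!is.null(cfg$classifier)) cfg$classifier else "?",
        if (isTRUE(cfg$selection)) "(with feature selection)" else "(no feature selection)",
        "\n  ", length(object@foldConfusions), "folds; pooled: ")
    show(object@pooled)
    m <- object@metrics
    cat(sprintf("  accuracy %.3f%%, MCC %.3f, MSE %.3g\n",
                m[["accuracy"]], m[["mcc"]],
                if ("mse" %in% names(m)) m[["mse"]] else NA_real_))
})
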