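#' Class labels of the samples
#'
#' @param x a [MicroarrayExperiment-class].
#' @return integer vector, 1 = cancer, 0 = normal.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "MicroarrayExperiment", function(x)
    as.integer(SummarizedExperiment::colData(x)$label))

#' Expression intensity matrix
#'
#' @param x a [MicroarrayExperiment-class].
#' @return numeric genes x samples matrix.
#' @export
setGeneric("exprsValues", function(x) standardGeneric("exprsValues"))

#' @rdname exprsValues
#' @export
setMethod("exprsValues", "MicroarrayExperiment", function(x)
    SummarizedExperiment::assay(x, "exprs"))

#' Simulated differential-expression ground truth
#'
#' @param x a [MicroarrayExperiment-class].
#' @return integer vector per gene (1 = simulated DE), or NULL for
#'   non-synthetic data.
#' @export
setGeneric("deTruth", function(x) standardGeneric("deTruth"))

#' @rdname deTruth
#' @export
setMethod("deTruth", "MicroarrayExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if ("de_truth" %in% colnames(rd)) as.integer(rd$de_truth) else NULL
})

#' Feature matrix of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return numeric samples x features matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureSet", function(x) x@values)

#' Extraction method tag of a FeatureSet
#'
#' @param x a [FeatureSet-class].
#' @return character scalar in {"FCM","SDA","HILBERT","FFT","DCT"}.
#' @export
setGeneric("featureMethod", function(x) standardGeneric("featureMethod"))

#' @rdname featureMethod
#' @export
setMethod("featureMethod", "FeatureSet", function(x) x@method)

#' Selected gene indices of a GeneSelection
#'
#' @param x a [GeneSelection-class].
#' @return sorted integer vector of retained gene indices.
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname selectedGenes
#' @export
setMethod("selectedGenes", "GeneSelection", function(x) x@selectedIdx)

#' Pooled confusion matrix of a cross-validation result
#'
#' @param x a [CrossValidationResult-class].
#' @return a [ConfusionMatrix-class].
#' @export
setGeneric("pooledConfusion", function(x) standardGeneric("pooledConfusion"))

#' @rdname pooledConfusion
#' @export
setMethod("pooledConfusion", "CrossValidationResult", function(x) x@pooled)

#' Metric report of a cross-validation result
#'
#' @param x a [CrossValidationResult-class].
#' @return named numeric vector (nine-metric report plus mean fold MSE).
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname cvMetrics
#' @export
setMethod("cvMetrics", "CrossValidationResult", function(x) x@metrics)
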