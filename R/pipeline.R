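#' Pipeline configuration
#'
#' Bundles every knob of a pipeline run: the data source (a
#' [MicroarrayExperiment-class], an expression file path, or a
#' [syntheticConfig()]), the gene-selection fraction, the feature method
#' and dimensions, the feature-selection setting, the classifier and its
#' hyperparameters, the cross-validation fold count and the master seed.
#' One seed governs the whole run: fold assignment and every stochastic
#' initializer derive from it.
#'
#' @param data a MicroarrayExperiment, a file path, or a syntheticConfig
#'   (default: the desk-scale synthetic configuration).
#' @param featureMethod one of "FCM", "SDA", "HILBERT", "FFT", "DCT".
#' @param classifier one of "GMM", "DFA", "NLR", "BLDC", "LR", "KNN".
#' @param selection logical, correlation-distance feature selection on/off.
#' @param geneFraction ANOVA gene-selection fraction (default 16000/33000).
#' @param fcmC,nFeatures,lambda extraction parameters (NULL = defaults).
#' @param selectK,selectMethod feature-selection parameters.
#' @param k cross-validation folds (default 10).
#' @param Q,K classifier hyperparameters.
#' @param seed master seed (default 0).
#' @param outDir optional output directory for written artifacts.
#' @return validated list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(data = syntheticConfig(),
                           featureMethod = "FCM", classifier = "LR",
                           selection = FALSE,
                           geneFraction = 16000 / 33000, fcmC = NULL,
                           nFeatures = NULL, lambda = 1, selectK = 45,
                           selectMethod = "pearson_distance", k = 10,
                           Q = 1, K = 3, seed = 0, outDir = NULL) {
    featureMethod <- match.arg(featureMethod,
                               c("FCM", "SDA", "HILBERT", "FFT", "DCT"),
                               several.ok = TRUE)
    classifier <- match.arg(classifier,
                            c("GMM", "DFA", "NLR", "BLDC", "LR", "KNN"),
                            several.ok = TRUE)
    if (is.character(data) && !file.exists(data))
        stop("configuration error: input file '", data, "' does not exist")
    structure(list(data = data, featureMethod = featureMethod,
                   classifier = classifier, selection = selection,
                   geneFraction = geneFraction, fcmC = fcmC,
                   nFeatures = nFeatures, lambda = lambda,
                   selectK = selectK, selectMethod = selectMethod, k = k,
                   Q = Q, K = K, seed = as.integer(seed), outDir = outDir),
              class = "pipelineConfig")
}

resolveData <- function(config) {
    d <- config$data
    if (is(d, "MicroarrayExperiment")) d
    else if (is.character(d)) readExpression(d)
    else simulateMicroarray(d)
}

#' Run the full pipeline for one configuration
#'
#' Simulates or loads the expression matrix, then cross-validates the
#' configured (feature method, classifier, selection) cell. When
#' \code{config$outDir} is set, writes the metric report as CSV and JSON
#' plus a plain-text run log echoing the configuration and seed; identical
#' configurations produce byte-identical metric files.
#'
#' @param config a [pipelineConfig()].
#' @return A [CrossValidationResult-class].
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(data = syntheticConfig(nGenes = 300, nPerClass = 15),
#'                       featureMethod = "DCT", classifier = "LR", k = 5)
#' res <- runPipeline(cfg)
#' pooledConfusion(res)
#' }
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    me <- resolveData(config)
    res <- crossValidate(me, config$featureMethod[1], config$classifier[1],
                         selection = config$selection[1], k = config$k,
                         seed = config$seed,
                         geneFraction = config$geneFraction,
                         fcmC = config$fcmC, nFeatures = config$nFeatures,
                         lambda = config$lambda, selectK = config$selectK,
                         selectMethod = config$selectMethod,
                         Q = config$Q, K = config$K)
    if (!is.null(config$outDir)) writeRunArtifacts(res, config)
    res
}

writeRunArtifacts <- function(res, config) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    row <- resultRow(res)
    utils::write.csv(row, file.path(config$outDir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
        list(config = config[setdiff(names(config), c("data", "outDir"))],
             pooled = list(tp = res@pooled@tp, tn = res@pooled@tn,
                           fp = res@pooled@fp, fn = res@pooled@fn),
             metrics = as.list(res@metrics)),
        file.path(config$outDir, "metrics.json"),
        auto_unbox = TRUE, digits = NA)
    log <- c("pipeline run",
             paste0("seed: ", config$seed),
             paste0("feature method: ", config$featureMethod[1]),
             paste0("classifier: ", config$classifier[1]),
             paste0("feature selection: ", config$selection[1]),
             paste0("folds: ", config$k),
             paste0("pooled confusion: TP=", res@pooled@tp,
                    " TN=", res@pooled@tn, " FP=", res@pooled@fp,
                    " FN=", res@pooled@fn))
    writeLines(log, file.path(config$outDir, "run.log"))
    invisible(NULL)
}

resultRow <- function(res) {
    cfg <- res@config
    m <- res@metrics
    data.frame(feature = cfg$featureMethod, classifier = cfg$classifier,
               selection = cfg$selection,
               tp = res@pooled@tp, tn = res@pooled@tn,
               fp = res@pooled@fp, fn = res@pooled@fn,
               mse = m[["mse"]],
               accuracy = round(m[["accuracy"]], 3),
               precision = round(m[["precision"]], 3),
               f1 = round(m[["f1"]], 3),
               mcc = round(m[["mcc"]], 3),
               fm = round(m[["fm"]], 3),
               error_rate = round(m[["error_rate"]], 3),
               jaccard = round(m[["jaccard"]], 3),
               csi = round(m[["csi"]], 3))
}

#' Run the (feature method x classifier x selection) experiment grid
#'
#' Cross-validates every combination of the requested feature methods,
#' classifiers and selection settings under a shared fold assignment,
#' re-using each fold's gene selection and feature extraction across
#' classifiers (the full default grid is 5 x 6 x 2 = 60 cells, the layout
#' of the published benchmark tables).
#'
#' @param config a [pipelineConfig()]; \code{featureMethod},
#'   \code{classifier} and \code{selection} may be vectors.
#' @param featureMethods,classifiers,selections optional overrides of the
#'   grid axes (defaults: all five methods, all six classifiers, the
#'   config's selection settings).
#' @return data.frame with one row per cell: feature, classifier,
#'   selection, pooled tp/tn/fp/fn, mean fold mse, and the eight derived
#'   metrics rounded to 3 decimals.
#' @export
runGrid <- function(config = pipelineConfig(),
                    featureMethods = c("FCM", "SDA", "HILBERT", "FFT",
                                       "DCT"),
                    classifiers = c("GMM", "DFA", "NLR", "BLDC", "LR",
                                    "KNN"),
                    selections = NULL) {
    stopifnot(inherits(config, "pipelineConfig"))
    if (is.null(selections)) selections <- unique(config$selection)
    me <- resolveData(config)
    labels <- classLabels(me)
    folds <- stratifiedFolds(labels, k = config$k, seed = config$seed)
    cells <- cvEngine(me, folds, featureMethods, classifiers, selections,
                      geneFraction = config$geneFraction, fcmC = config$fcmC,
                      nFeatures = config$nFeatures, lambda = config$lambda,
                      selectK = config$selectK,
                      selectMethod = config$selectMethod,
                      Q = config$Q, K = config$K, seed = config$seed)
    rows <- lapply(cells, function(cell) {
        res <- cellToResult(cell, folds, config$seed,
                            list(featureMethod = cell$feature,
                                 classifier = cell$classifier,
                                 selection = cell$selection))
        resultRow(res)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(out, file.path(config$outDir, "grid.csv"),
                         row.names = FALSE)
    }
    out
}

#' Serialize a FeatureSet as delimited text with a JSON sidecar
#'
#' @param f a [FeatureSet-class].
#' @param path output file (samples as rows, header = feature ids); the
#'   sidecar \code{<path>.json} records method and provenance.
#' @return invisibly, \code{path}.
#' @export
writeFeatureSet <- function(f, path) {
    stopifnot(is(f, "FeatureSet"))
    utils::write.table(data.frame(sample_id = rownames(featureValues(f)),
                                  featureValues(f), check.names = FALSE),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(method = featureMethod(f),
                              provenance = f@provenance),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}
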