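#' Build a confusion matrix from counts or from label vectors
#'
#' @param tp,tn,fp,fn non-negative counts; alternatively supply
#'   \code{truth} and \code{predicted} binary vectors.
#' @param truth,predicted binary label vectors (1 = cancer positive class).
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionMatrix(truth = c(1, 1, 0, 0), predicted = c(1, 0, 0, 1))
#' @export
confusionMatrix <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                            truth = NULL, predicted = NULL) {
    if (!is.null(truth)) {
        stopifnot(length(truth) == length(predicted))
        tp <- sum(truth == 1 & predicted == 1)
        tn <- sum(truth == 0 & predicted == 0)
        fp <- sum(truth == 0 & predicted == 1)
        fn <- sum(truth == 1 & predicted == 0)
    }
    new("ConfusionMatrix", tp = as.numeric(tp), tn = as.numeric(tn),
        fp = as.numeric(fp), fn = as.numeric(fn))
}

#' Nine-metric report from a confusion matrix
#'
#' Derives the standard confusion-matrix performance report: accuracy,
#' precision, F1, error rate, Jaccard and CSI on the percent scale;
#' Matthews correlation coefficient (in [-1, 1]) and the Fowlkes-Mallows
#' index (in [0, 1]) unitless. CSI (classification success index) is
#' precision + sensitivity - 100. Any metric whose denominator is zero is
#' reported as 0 and named in the \code{"flags"} attribute. Values are
#' returned at full precision; round to 3 decimals for display.
#'
#' @param cm a [ConfusionMatrix-class] (or tp/tn/fp/fn counts).
#' @param tn,fp,fn counts, if \code{cm} is given as the tp count.
#' @return named numeric: accuracy, precision, f1, mcc, fm, error_rate,
#'   jaccard, csi, with attribute \code{flags}.
#' @examples
#' round(metricsFromConfusion(confusionMatrix(48, 44, 6, 2)), 3)
#' @export
metricsFromConfusion <- function(cm, tn = NULL, fp = NULL, fn = NULL) {
    if (!is(cm, "ConfusionMatrix")) cm <- confusionMatrix(cm, tn, fp, fn)
    tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
    total <- tp + tn + fp + fn
    flags <- character(0)
    safe <- function(num, den, name) {
        if (den == 0) { flags <<- c(flags, name); 0 } else num / den
    }
    precision <- 100 * safe(tp, tp + fp, "precision")
    sensitivity <- safe(tp, tp + fn, "sensitivity")
    mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    out <- c(accuracy = 100 * (tp + tn) / total,
             precision = precision,
             f1 = 100 * safe(2 * tp, 2 * tp + fp + fn, "f1"),
             mcc = if (mccDen == 0) { flags <- c(flags, "mcc"); 0 }
                   else (tp * tn - fp * fn) / mccDen,
             fm = sqrt(precision / 100 * sensitivity),
             error_rate = 100 * (fp + fn) / total,
             jaccard = 100 * safe(tp, tp + fp + fn, "jaccard"),
             csi = precision + 100 * sensitivity - 100)
    attr(out, "flags") <- unique(flags)
    out
}

#' Mean squared error between scores and targets
#'
#' @param scores,targets numeric vectors of equal length.
#' @return mean of squared differences.
#' @export
mseScores <- function(scores, targets) {
    if (length(scores) != length(targets))
        stop("scores and targets must have equal length")
    mean((scores - targets)^2)
}

#' Seeded stratified k-fold partition
#'
#' Splits samples into k folds preserving the class proportions: within
#' each class the (seeded) shuffled samples are dealt round-robin to the
#' folds, so with class counts divisible by k every fold has equal class
#' counts.
#'
#' @param labels binary class labels.
#' @param k number of folds (each class count must be >= k).
#' @param seed integer seed.
#' @return list of k integer vectors of test-sample indices (disjoint,
#'   covering all samples).
#' @export
stratifiedFolds <- function(labels, k = 10, seed = 1) {
    counts <- table(labels)
    if (any(counts < k))
        stop("each class needs >= k samples; reduce k (largest feasible: ",
             min(counts), ")")
    withr::with_seed(seed, {
        fold <- integer(length(labels))
        for (cl in names(counts)) {
            idx <- sample(which(labels == as.numeric(cl)))
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
        lapply(unname(split(seq_along(labels), fold)), unname)
    })
}

# run one fold x method x selection x classifier cell; internal engine used
# by crossValidate() and runGrid(). Returns per-cell accumulators.
cvEngine <- function(me, folds, methods, classifiers, selections,
                     geneFraction = 16000 / 33000, fcmC = NULL,
                     nFeatures = NULL, lambda = 1, selectK = 45,
                     selectMethod = "pearson_distance",
                     encoding = targetEncoding(), Q = 1, K = 3, seed = 1) {
    labels <- classLabels(me)
    cellKey <- function(m, cl, s) paste(m, cl, s, sep = "|")
    cells <- list()
    for (m in methods) for (cl in classifiers) for (s in selections)
        cells[[cellKey(m, cl, s)]] <- list(
            feature = m, classifier = cl, selection = s,
            tp = 0, tn = 0, fp = 0, fn = 0, foldMse = numeric(0),
            foldConfusions = list())
    for (f in seq_along(folds)) {
        testIdx <- folds[[f]]
        trainIdx <- setdiff(seq_along(labels), testIdx)
        sub <- me[, trainIdx]
        gs <- selectProminent(anovaVolcano(sub), "fraction_by_p",
                              fraction = geneFraction)
        mat <- prominentMatrix(me, gs)
        for (m in methods) {
            fs <- switch(m,
                FCM = fcmFeatures(mat, trainIdx = trainIdx, C = fcmC,
                                  seed = seed),
                SDA = sdaFeatures(mat, labels, trainIdx = trainIdx,
                                  nFeatures = nFeatures, lambda = lambda),
                HILBERT = hilbertFeatures(mat, nFeatures = nFeatures),
                FFT = fftFeatures(mat, nFeatures = nFeatures),
                DCT = dctFeatures(mat, nFeatures = nFeatures))
            v <- featureValues(fs)
            for (s in selections) {
                if (s) {
                    k <- min(selectK, ncol(v))
                    sel <- selectByCorrelationDistance(v, labels, k = k,
                                                       method = selectMethod,
                                                       trainIdx = trainIdx)
                    vUse <- v[, sel$keptIdx, drop = FALSE]
                } else vUse <- v
                for (cl in classifiers) {
                    model <- fitClassifier(vUse[trainIdx, , drop = FALSE],
                                           labels[trainIdx], cl,
                                           encoding = encoding, Q = Q, K = K,
                                           seed = seed)
                    pred <- predict(model, vUse[testIdx, , drop = FALSE])
                    cmF <- confusionMatrix(truth = labels[testIdx],
                                           predicted = pred$label)
                    key <- cellKey(m, cl, s)
                    cell <- cells[[key]]
                    cell$tp <- cell$tp + cmF@tp; cell$tn <- cell$tn + cmF@tn
                    cell$fp <- cell$fp + cmF@fp; cell$fn <- cell$fn + cmF@fn
                    cell$foldMse <- c(cell$foldMse,
                                      mseScores(pred$score,
                                                encodeTargets(labels[testIdx],
                                                              encoding)))
                    cell$foldConfusions <- c(cell$foldConfusions, list(cmF))
                    cells[[key]] <- cell
                }
            }
        }
    }
    cells
}

#' Stratified k-fold cross-validation of one pipeline cell
#'
#' Runs the full pipeline for one (feature method, classifier, selection
#' on/off) combination under seeded stratified k-fold cross-validation.
#' Every data-dependent stage -- gene selection, feature-extraction model
#' fitting, correlation-distance feature selection, classifier fitting --
#' sees only the training 90\% of each fold; confusion counts are
#' accumulated from the held-out 10\%. The headline confusion matrix is
#' pooled over folds (it sums to the full sample count); per-fold
#' confusions and the mean per-fold score MSE are also reported.
#'
#' @param me a [MicroarrayExperiment-class].
#' @param featureMethod one of "FCM", "SDA", "HILBERT", "FFT", "DCT".
#' @param classifier one of "GMM", "DFA", "NLR", "BLDC", "LR", "KNN".
#' @param selection logical: apply correlation-distance feature selection.
#' @param k number of folds (default 10).
#' @param seed integer seed driving the fold assignment and any stochastic
#'   initializer.
#' @param geneFraction fraction of genes kept by ANOVA p-value (default
#'   16000/33000).
#' @param fcmC,nFeatures,lambda feature-extraction parameters (NULL =
#'   ratio-preserving defaults).
#' @param selectK features kept by correlation distance (default 45,
#'   capped at the feature count).
#' @param selectMethod correlation-distance variant.
#' @param encoding a [targetEncoding()].
#' @param Q,K classifier hyperparameters (GMM components, KNN neighbours).
#' @return A [CrossValidationResult-class].
#' @export
crossValidate <- function(me, featureMethod, classifier, selection = FALSE,
                          k = 10, seed = 1, geneFraction = 16000 / 33000,
                          fcmC = NULL, nFeatures = NULL, lambda = 1,
                          selectK = 45, selectMethod = "pearson_distance",
                          encoding = targetEncoding(), Q = 1, K = 3) {
    labels <- classLabels(me)
    folds <- stratifiedFolds(labels, k = k, seed = seed)
    cells <- cvEngine(me, folds, featureMethod, classifier, selection,
                      geneFraction = geneFraction, fcmC = fcmC,
                      nFeatures = nFeatures, lambda = lambda,
                      selectK = selectK, selectMethod = selectMethod,
                      encoding = encoding, Q = Q, K = K, seed = seed)
    cellToResult(cells[[1]], folds, seed,
                 list(featureMethod = featureMethod, classifier = classifier,
                      selection = selection, k = k,
                      geneFraction = geneFraction, selectK = selectK,
                      selectMethod = selectMethod))
}

cellToResult <- function(cell, folds, seed, config) {
    pooled <- confusionMatrix(cell$tp, cell$tn, cell$fp, cell$fn)
    metrics <- c(metricsFromConfusion(pooled), mse = mean(cell$foldMse))
    new("CrossValidationResult", foldConfusions = cell$foldConfusions,
        pooled = pooled, metrics = metrics, folds = folds,
        seed = as.integer(seed), config = config)
}

#' Audit a printed metric table against its confusion matrices
#'
#' Recomputes the nine-metric report from each row's TP/TN/FP/FN counts and
#' flags every printed value differing from the derived one by more than
#' 0.001 (percent-scale metrics) or 0.0005 (MCC and Fowlkes-Mallows).
#'
#' @param confusions data.frame with columns tp, tn, fp, fn (one row per
#'   table row).
#' @param printedMetrics data.frame with columns accuracy, precision, f1,
#'   mcc, fm, error_rate, jaccard, csi, paired row-for-row with
#'   \code{confusions}.
#' @return data.frame of discrepancies (row, metric, derived, printed,
#'   diff); zero rows when the table is consistent.
#' @examples
#' tab <- benchmarkTable("none")
#' nrow(auditMetricTable(tab, tab))   # published table is self-consistent
#' @export
auditMetricTable <- function(confusions, printedMetrics) {
    if (nrow(confusions) != nrow(printedMetrics))
        stop("confusions and printedMetrics must be paired row-for-row")
    metricNames <- c("accuracy", "precision", "f1", "mcc", "fm",
                     "error_rate", "jaccard", "csi")
    tol <- c(accuracy = 0.001, precision = 0.001, f1 = 0.001, mcc = 0.0005,
             fm = 0.0005, error_rate = 0.001, jaccard = 0.001, csi = 0.001)
    out <- list()
    for (i in seq_len(nrow(confusions))) {
        derived <- metricsFromConfusion(confusionMatrix(
            confusions$tp[i], confusions$tn[i], confusions$fp[i],
            confusions$fn[i]))
        for (nm in metricNames) {
            printed <- printedMetrics[[nm]][i]
            if (is.null(printed) || is.na(printed)) next
            diff <- abs(derived[[nm]] - printed)
            if (diff > tol[[nm]])
                out[[length(out) + 1L]] <- data.frame(
                    row = i, metric = nm, derived = derived[[nm]],
                    printed = printed, diff = diff)
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(row = integer(0), metric = character(0),
                    derived = numeric(0), printed = numeric(0),
                    diff = numeric(0))
}

#' Published benchmark tables of the ovarian-cancer microarray study
#'
#' Confusion matrices (TP/TN/FP/FN), per-cell MSE and the printed
#' nine-metric report for all 30 (feature method x classifier) cells of the
#' original 100-sample ovarian-cancer microarray benchmark, with and
#' without correlation-distance feature selection. Shipped as plain-text
#' fixtures; used by [auditMetricTable()] and the test-suite consistency
#' checks.
#'
#' @param selection "none" or "correlation" -- which experimental arm.
#' @return data.frame with columns feature, classifier, tp, tn, fp, fn,
#'   mse, accuracy, precision, f1, mcc, fm, error_rate, jaccard, csi.
#' @export
benchmarkTable <- function(selection = c("none", "correlation")) {
    selection <- match.arg(selection)
    file <- system.file("extdata",
                        if (selection == "none") "benchmark_no_selection.csv"
                        else "benchmark_with_selection.csv",
                        package = "ovaclass", mustWork = TRUE)
    utils::read.csv(file, stringsAsFactors = FALSE)
}
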