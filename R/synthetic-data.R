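#' Configuration for the synthetic microarray generator
#'
#' Bundles and validates the parameters of [simulateMicroarray()]. The
#' defaults emulate the study design the pipeline targets: two balanced
#' classes of 50 samples each and a differentially expressed subset whose
#' up/down split produces the two tails of a volcano plot, with heavy-tailed
#' (Student-t) log-scale noise. The desk-scale default of 2,000 genes keeps
#' simulations fast; the full 33,000-gene scale is supported by setting
#' \code{nGenes}.
#'
#' @param nGenes number of genes (rows). Default 2000.
#' @param nPerClass samples per class (two classes). Default 50.
#' @param deFraction fraction in (0, 1) of genes simulated as differentially
#'   expressed. Default 0.1.
#' @param effectSize mean absolute log2 fold change of DE genes. Default 2.
#' @param baseLogMean baseline log2 intensity. Default 6.
#' @param noiseSd log2-scale noise standard deviation (> 0). Default 0.5.
#' @param tailDf degrees of freedom of the Student-t noise (> 2; smaller =
#'   heavier tails). Default 5.
#' @param geneSd standard deviation of per-gene baseline offsets around
#'   \code{baseLogMean}. Default 1.
#' @param seed integer RNG seed. Default 1.
#' @return A validated list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(nGenes = 2000, nPerClass = 50, deFraction = 0.1,
                            effectSize = 2, baseLogMean = 6, noiseSd = 0.5,
                            tailDf = 5, geneSd = 1, seed = 1) {
    chk <- function(ok, field, what)
        if (!ok) stop("invalid configuration: '", field, "' ", what,
                      call. = FALSE)
    chk(is.numeric(nGenes) && nGenes >= 1, "nGenes", "must be a count >= 1")
    chk(is.numeric(nPerClass) && nPerClass >= 1, "nPerClass",
        "must be a count >= 1")
    chk(is.numeric(deFraction) && deFraction > 0 && deFraction < 1,
        "deFraction", "must lie in (0, 1)")
    chk(is.numeric(effectSize) && effectSize >= 0, "effectSize",
        "must be >= 0")
    chk(is.numeric(noiseSd) && noiseSd > 0, "noiseSd", "must be > 0")
    chk(is.numeric(tailDf) && tailDf > 2, "tailDf", "must be > 2")
    chk(is.numeric(geneSd) && geneSd >= 0, "geneSd", "must be >= 0")
    structure(list(nGenes = as.integer(nGenes),
                   nPerClass = as.integer(nPerClass),
                   deFraction = deFraction, effectSize = effectSize,
                   baseLogMean = baseLogMean, noiseSd = noiseSd,
                   tailDf = tailDf, geneSd = geneSd,
                   seed = as.integer(seed)),
              class = "syntheticConfig")
}

#' Simulate a labeled microarray expression matrix
#'
#' Generates a genes x samples intensity matrix with the structure the
#' downstream pipeline assumes. On the log2 scale each gene has a baseline
#' drawn around \code{baseLogMean}; exactly
#' \code{round(deFraction * nGenes)} genes receive a class-dependent mean
#' shift of +/- \code{effectSize} in the cancer class (sign random, 50/50,
#' recorded in \code{deTruth}); heavy-tailed noise is Student-t with
#' \code{tailDf} degrees of freedom, scaled so its standard deviation is
#' \code{noiseSd}. Intensities are \code{2^log2value}, i.e. already
#' normalized positive intensities. The function is a pure function of its
#' configuration: identical config (including seed) gives bit-identical
#' output, and the caller's RNG state is left untouched.
#'
#' @param config a [syntheticConfig()] list.
#' @return A [MicroarrayExperiment-class] with \code{deTruth} filled in.
#' @examples
#' me <- simulateMicroarray(syntheticConfig(nGenes = 200, nPerClass = 10))
#' table(classLabels(me))
#' @export
simulateMicroarray <- function(config = syntheticConfig()) {
    if (!inherits(config, "syntheticConfig"))
        config <- do.call(syntheticConfig, config)
    withr::with_seed(config$seed, {
        g <- config$nGenes
        n <- 2L * config$nPerClass
        labels <- rep(c(0L, 1L), each = config$nPerClass)
        nde <- round(config$deFraction * g)
        deIdx <- sample.int(g, nde)
        sign <- sample(c(-1, 1), nde, replace = TRUE)
        baseline <- config$baseLogMean + rnorm(g, 0, config$geneSd)
        shift <- numeric(g)
        shift[deIdx] <- sign * config$effectSize
        tScale <- config$noiseSd / sqrt(config$tailDf / (config$tailDf - 2))
        noise <- matrix(rt(g * n, df = config$tailDf) * tScale, g, n)
        logv <- baseline + outer(shift, as.numeric(labels)) + noise
        deTruth <- integer(g)
        deTruth[deIdx] <- 1L
        MicroarrayExperiment(2^logv, labels = labels, deTruth = deTruth)
    })
}

#' Write / read a labeled expression matrix as delimited text
#'
#' The on-disk layout is genes as rows: a header line of sample ids whose
#' first field is \code{gene_id}, a second header line whose first field is
#' \code{label} carrying the binary class labels, then one row per gene.
#' \code{readExpression} auto-detects tab or comma delimiters and also
#' accepts a sidecar labels file (two columns: sample_id, label) in place of
#' the embedded label line.
#'
#' @param x a [MicroarrayExperiment-class].
#' @param path file to write / read.
#' @param sep field delimiter for writing ("\t" or ",").
#' @param labelsPath optional sidecar labels file; when supplied to
#'   \code{writeExpression} labels are written there instead of as a second
#'   header line, and \code{readExpression} reads them from it.
#' @return \code{writeExpression}: invisibly, \code{path}.
#'   \code{readExpression}: a [MicroarrayExperiment-class].
#' @export
writeExpression <- function(x, path, sep = "\t", labelsPath = NULL) {
    stopifnot(is(x, "MicroarrayExperiment"))
    v <- exprsValues(x)
    lab <- classLabels(x)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(v)), collapse = sep), con)
    if (is.null(labelsPath)) {
        writeLines(paste(c("label", lab), collapse = sep), con)
    } else {
        utils::write.table(data.frame(sample_id = colnames(v), label = lab),
                           labelsPath, sep = sep, row.names = FALSE,
                           quote = FALSE)
    }
    utils::write.table(data.frame(gene_id = rownames(v), v,
                                  check.names = FALSE),
                       con, sep = sep, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path, labelsPath = NULL) {
    lines <- readLines(path)
    if (length(lines) < 2L)
        stop("parse error: file has fewer than 2 lines")
    sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0)
        "\t" else ","
    fields <- strsplit(lines, sep, fixed = TRUE)
    widths <- lengths(fields)
    if (any(widths != widths[1]))
        stop("parse error: ragged rows, row ", which(widths != widths[1])[1],
             " has ", widths[widths != widths[1]][1], " fields, expected ",
             widths[1])
    header <- fields[[1]]
    sampleIds <- header[-1]
    dataStart <- 2L
    lab <- NULL
    if (identical(fields[[2]][1], "label")) {
        lab <- suppressWarnings(as.numeric(fields[[2]][-1]))
        if (anyNA(lab)) stop("parse error: non-numeric label in header row 2")
        dataStart <- 3L
    }
    if (!is.null(labelsPath)) {
        labTab <- utils::read.table(labelsPath, header = TRUE,
                                    sep = sep, stringsAsFactors = FALSE)
        lab <- labTab[[2]][match(sampleIds, labTab[[1]])]
        if (anyNA(lab))
            stop("parse error: labels file is missing entries for some samples")
    }
    if (is.null(lab))
        stop("parse error: no labels found (expected a 'label' header row ",
             "or a labelsPath sidecar file)")
    body <- fields[seq(dataStart, length(fields))]
    geneIds <- vapply(body, `[[`, character(1), 1L)
    values <- matrix(NA_real_, length(body), length(sampleIds))
    for (i in seq_along(body)) {
        row <- suppressWarnings(as.numeric(body[[i]][-1]))
        if (anyNA(row)) {
            j <- which(is.na(row))[1]
            stop("parse error: non-numeric cell at row ", i, ", col ", j,
                 " (value '", body[[i]][j + 1L], "')")
        }
        values[i, ] <- row
    }
    MicroarrayExperiment(values, geneIds = geneIds, sampleIds = sampleIds,
                         labels = lab)
}
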