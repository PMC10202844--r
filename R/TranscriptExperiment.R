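#' Construct a TranscriptExperiment
#'
#' Bundles a transcript x sample count matrix, the transcript-to-gene
#' mapping, and the per-sample study covariates into a validated
#' [TranscriptExperiment-class].
#'
#' @param counts integer matrix, transcripts x samples, with rownames
#'   (transcript ids) and colnames (sample ids).
#' @param geneSymbols character vector, one gene symbol per transcript.
#' @param design data.frame with columns `sample_id`, `group` (CON/MNR),
#'   `sex` (F/M) and `gestational_day`; rows must cover the matrix columns
#'   exactly (order is taken from the count matrix).
#' @return A [TranscriptExperiment-class].
#' @examples
#' sim <- simulateCounts(simulationSpec(nGenes = 20, seed = 1))
#' sim$experiment
#' @export
TranscriptExperiment <- function(counts, geneSymbols, design) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (!is.data.frame(design) ||
        !all(c("sample_id", "group", "sex", "gestational_day") %in% names(design)))
        stop("design needs columns sample_id, group, sex, gestational_day")
    if (anyDuplicated(design$sample_id))
        stop("duplicate sample_id in design")
    if (!setequal(design$sample_id, colnames(counts)) ||
        nrow(design) != ncol(counts))
        stop("design sample_ids must exactly cover the count-matrix columns")
    design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(
        group = as.character(design$group),
        sex = as.character(design$sex),
        gestational_day = as.numeric(design$gestational_day),
        row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_symbol = as.character(geneSymbols),
                                       row.names = rownames(counts)),
        colData = cd)
    new("TranscriptExperiment", se)
}

#' @rdname TranscriptExperiment
#' @param x a `TranscriptExperiment`.
#' @export
geneSymbols <- function(x) {
    as.character(SummarizedExperiment::rowData(x)$gene_symbol)
}

#' @rdname TranscriptExperiment
#' @export
studyDesign <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(sample_id = rownames(cd), group = cd$group, sex = cd$sex,
               gestational_day = cd$gestational_day,
               stringsAsFactors = FALSE, row.names = NULL)
}

setMethod("show", "TranscriptExperiment", function(object) {
    cat("TranscriptExperiment:", nrow(object), "transcripts x",
        ncol(object), "samples\n")
    cat("  genes:", length(unique(geneSymbols(object))), "\n")
    d <- studyDesign(object)
    tab <- table(d$group, d$gestational_day)
    cat("  samples per group x gestational day:\n")
    print(tab)
    invisible(NULL)
})

setMethod("show", "WeightedExpression", function(object) {
    cat("WeightedExpression:", nrow(object@logcpm), "transcripts x",
        ncol(object@logcpm), "samples\n")
    cat(sprintf("  weight range: [%.3g, %.3g]\n",
                min(object@weights), max(object@weights)))
    invisible(NULL)
})

setMethod("show", "DEResult", function(object) {
    cat("DEResult over", nrow(object@contrasts[[1L]]), "transcripts\n")
    cat(sprintf("  prior df d0 = %.4g, prior variance s0^2 = %.4g\n",
                object@priorDf, object@priorVar))
    for (nm in names(object@contrasts)) {
        tab <- object@contrasts[[nm]]
        cat(sprintf("  %-8s: %d transcripts at FDR < 0.1\n", nm,
                    sum(tab$fdr < 0.1)))
    }
    invisible(NULL)
})

setMethod("show", "SpliceMetaResult", function(object) {
    cat("SpliceMetaResult:", nrow(object@meta), "genes meta-analysed over",
        length(object@perTimepoint), "timepoints\n")
    g <- object@global
    cat(sprintf("  global shift: mean Z = %.3f, skewness = %.3f, p = %.3g\n",
                g$mean, g$skewness, g$p))
    invisible(NULL)
})

#' Accessors for result objects
#'
#' `deTable()` returns one contrast table (or all three), `spliceMeta()` the
#' per-gene meta-analysis table, `spliceGlobal()` the global shift summary,
#' and `priorDf()` / `priorVar()` the empirical-Bayes hyperparameters.
#'
#' @param x a [DEResult-class] or [SpliceMetaResult-class].
#' @param contrast for `deTable`, one of `"MNR"`, `"MNR.t"`, `"MNR.t2"`, or
#'   `NULL` for the named list of all three.
#' @export
deTable <- function(x, contrast = NULL) {
    stopifnot(is(x, "DEResult"))
    if (is.null(contrast)) return(x@contrasts)
    x@contrasts[[match.arg(contrast, names(x@contrasts))]]
}

#' @rdname deTable
#' @export
priorDf <- function(x) x@priorDf

#' @rdname deTable
#' @export
priorVar <- function(x) x@priorVar

#' @rdname deTable
#' @export
spliceMeta <- function(x) {
    stopifnot(is(x, "SpliceMetaResult"))
    x@meta
}

#' @rdname deTable
#' @export
spliceGlobal <- function(x) {
    stopifnot(is(x, "SpliceMetaResult"))
    x@global
}

#' @rdname deTable
#' @export
splicePerTimepoint <- function(x) {
    stopifnot(is(x, "SpliceMetaResult"))
    x@perTimepoint
}
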