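#' Transcript-level count container
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one `"counts"`
#' assay of non-negative integer transcript-level read counts, a
#' `gene_symbol` column in `rowData()` mapping each transcript to its gene
#' (many-to-one), and the study covariates `group` (CON/MNR), `sex` (F/M)
#' and `gestational_day` in `colData()`.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("TranscriptExperiment", contains = "SummarizedExperiment")

.validTranscriptExperiment <- function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
            msg <- c(msg, "counts must be finite non-negative integers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "transcript ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    rd <- SummarizedExperiment::rowData(object)
    if (!("gene_symbol" %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'gene_symbol'")
    else if (any(is.na(rd$gene_symbol)) || any(!nzchar(rd$gene_symbol)))
        msg <- c(msg, "every transcript needs a non-empty gene_symbol")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("group", "sex", "gestational_day"))
        if (!(col %in% colnames(cd)))
            msg <- c(msg, sprintf("colData must contain '%s'", col))
    if ("group" %in% colnames(cd) && !all(cd$group %in% c("CON", "MNR")))
        msg <- c(msg, "group must be 'CON' or 'MNR'")
    if ("sex" %in% colnames(cd) && !all(cd$sex %in% c("F", "M")))
        msg <- c(msg, "sex must be 'F' or 'M'")
    if ("gestational_day" %in% colnames(cd) &&
        (any(!is.finite(cd$gestational_day)) || any(cd$gestational_day <= 0)))
        msg <- c(msg, "gestational_day must be positive and finite")
    if (length(msg)) msg else TRUE
}
setValidity("TranscriptExperiment", .validTranscriptExperiment)

#' Observation-level precision weights
#'
#' Log2 counts-per-million together with per-observation precision weights
#' derived from the fitted mean-variance trend, as produced by
#' [voomWeights()].
#'
#' @slot logcpm numeric matrix (transcripts x samples) of
#'   `log2((count + 0.5) / (libsize + 1) * 1e6)`.
#' @slot weights strictly positive numeric matrix, same shape as `logcpm`.
#' @slot libSizes per-sample library sizes (column sums of raw counts).
#' @slot trend list with components `x` (mean log2-count) and `y`
#'   (sqrt residual sd), the lowess curve the weights interpolate.
#' @slot geneSymbols character, gene symbol per transcript row.
#' @export
setClass("WeightedExpression",
    representation(logcpm = "matrix", weights = "matrix",
                   libSizes = "numeric", trend = "list",
                   geneSymbols = "character"))

setValidity("WeightedExpression", function(object) {
    msg <- character()
    if (!identical(dim(object@logcpm), dim(object@weights)))
        msg <- c(msg, "logcpm and weights must share dimensions")
    if (any(!is.finite(object@logcpm)))
        msg <- c(msg, "logcpm must be finite")
    if (any(!is.finite(object@weights)) || any(object@weights <= 0))
        msg <- c(msg, "weights must be strictly positive and finite")
    if (length(object@libSizes) != ncol(object@logcpm))
        msg <- c(msg, "one library size per sample is required")
    if (length(msg)) msg else TRUE
})

#' Per-transcript weighted least-squares fits
#'
#' @slot coefficients transcripts x p matrix of WLS coefficients.
#' @slot stdevUnscaled transcripts x p matrix, sqrt of the diagonal of
#'   `(X' W X)^-1` per transcript.
#' @slot sigma2 residual variances (weighted RSS / residual df).
#' @slot df residual degrees of freedom (common to all transcripts).
#' @slot flagged logical; transcripts with numerically singular or
#'   zero-residual fits (excluded or variance-floored downstream).
#' @slot geneSymbols gene symbol per transcript.
#' @export
setClass("WeightedLMFit",
    representation(coefficients = "matrix", stdevUnscaled = "matrix",
                   sigma2 = "numeric", df = "numeric", flagged = "logical",
                   geneSymbols = "character"))

#' Moderated differential-expression results
#'
#' @slot contrasts named list of per-contrast data frames
#'   (`transcript_id`, `gene_symbol`, `coef`, `t_mod`, `p`, `fdr`),
#'   one each for the group main effect and the two group-by-time
#'   interactions.
#' @slot priorDf empirical-Bayes prior degrees of freedom (may be `Inf`).
#' @slot priorVar empirical-Bayes prior variance.
#' @slot sTilde per-transcript moderated residual sd.
#' @slot fit the underlying [WeightedLMFit-class].
#' @export
setClass("DEResult",
    representation(contrasts = "list", priorDf = "numeric",
                   priorVar = "numeric", sTilde = "numeric",
                   fit = "WeightedLMFit"))

#' Splice-variant diversity results
#'
#' @slot perTimepoint named list (one element per gestational day) of data
#'   frames `gene_symbol`, `beta`, `se`, `p`, `fdr`, `converged` from the
#'   per-timepoint Poisson regressions of expressed-isoform counts.
#' @slot meta data frame `gene_symbol`, `beta`, `se`, `z`, `p`, `fdr`,
#'   `n_studies` from the fixed-effect inverse-variance combination across
#'   the configured meta timepoints.
#' @slot global list with the distribution-shift summary on all meta
#'   Z-scores (`n`, `mean`, `skewness`, `t`, `p`) and the same on the
#'   subset with unadjusted p < 0.05 (`subset05`).
#' @slot excluded data frame of genes dropped from the meta analysis with
#'   a reason.
#' @export
setClass("SpliceMetaResult",
    representation(perTimepoint = "list", meta = "data.frame",
                   global = "list", excluded = "data.frame"))

#' Pipeline configuration
#'
#' Thresholds and options shared across the pipeline stages. Defaults
#' mirror the admission rules of the analysis: transcripts are removed when
#' their maximum count across samples is below `minMaxCount`; an isoform
#' counts as expressed at `presenceThreshold` reads; genes qualify as
#' primary candidates at FDR < `fdrPrimary` and enter the network set at
#' unadjusted p < `pNetwork`; complexes are admitted at MCODE score
#' strictly greater than `mcodeMinScore` with at least `mcodeMinNodes`
#' members ("more than six nodes").
#'
#' @export
setClass("PipelineConfig",
    representation(minMaxCount = "numeric", presenceThreshold = "numeric",
                   fdrPrimary = "numeric", pNetwork = "numeric",
                   fdrSplice = "numeric", metaTimepoints = "numeric",
                   mcodeVwp = "numeric", mcodeMinScore = "numeric",
                   mcodeMinNodes = "numeric", mcodeHaircut = "logical",
                   lowessSpan = "numeric", rngSeed = "numeric"),
    prototype(minMaxCount = 15, presenceThreshold = 1, fdrPrimary = 0.1,
              pNetwork = 0.001, fdrSplice = 0.05, metaTimepoints = c(120, 140),
              mcodeVwp = 0.2, mcodeMinScore = 4, mcodeMinNodes = 7,
              mcodeHaircut = TRUE, lowessSpan = 0.5, rngSeed = 1))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    pos <- c(minMaxCount = object@minMaxCount,
             presenceThreshold = object@presenceThreshold,
             mcodeMinScore = object@mcodeMinScore,
             mcodeMinNodes = object@mcodeMinNodes,
             lowessSpan = object@lowessSpan)
    if (any(!is.finite(pos)) || any(pos <= 0))
        msg <- c(msg, "all thresholds must be positive")
    for (nm in c("fdrPrimary", "pNetwork", "fdrSplice")) {
        v <- slot(object, nm)
        if (!is.finite(v) || v <= 0 || v >= 1)
            msg <- c(msg, sprintf("%s must lie in (0, 1)", nm))
    }
    if (object@mcodeVwp < 0 || object@mcodeVwp >= 1)
        msg <- c(msg, "mcodeVwp must lie in [0, 1)")
    if (length(object@metaTimepoints) < 1)
        msg <- c(msg, "at least one meta timepoint is required")
    if (length(msg)) msg else TRUE
})

#' Simulation specification
#'
#' Parameters of the synthetic transcript-count generator; defaults encode
#' the study conditions the pipeline targets (28 samples over gestational
#' days 90/120/140/165 with group sizes 8/8 at the endpoints and 6/6 at the
#' middle timepoints, equal sexes per group). See [simulateCounts()].
#'
#' @export
setClass("SimulationSpec",
    representation(nGenes = "numeric", isoLambda = "numeric",
                   baselineMean = "numeric", baselineSd = "numeric",
                   nbDispersion = "numeric", fracDe = "numeric",
                   deEffect = "numeric", fracSplice = "numeric",
                   spliceEffect = "numeric", affectedTimepoints = "numeric",
                   sexEffect = "numeric", libSd = "numeric",
                   design = "data.frame", seed = "numeric"),
    prototype(nGenes = 500, isoLambda = 3, baselineMean = 5, baselineSd = 2,
              nbDispersion = 0.1, fracDe = 0.1, deEffect = 1,
              fracSplice = 0.1, spliceEffect = 0.5,
              affectedTimepoints = c(120, 140), sexEffect = 0.2,
              libSd = 0.1, design = data.frame(), seed = 1))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
    if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
    for (nm in c("fracDe", "fracSplice")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
    }
    if (object@fracDe + object@fracSplice > 1)
        msg <- c(msg, "fracDe + fracSplice must not exceed 1 (disjoint gene sets)")
    if (object@spliceEffect < 0) msg <- c(msg, "spliceEffect must be >= 0")
    if (object@isoLambda < 0) msg <- c(msg, "isoLambda must be >= 0")
    if (length(msg)) msg else TRUE
})
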