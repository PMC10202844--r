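#' Read and write transcript-count tables
#'
#' The counts TSV is tab-separated UTF-8 with header
#' `transcript_id  gene_symbol  <sample...>` and an integer body; lines
#' starting with `#` are ignored (writers use them to record the
#' configuration snapshot).
#'
#' @param path file path.
#' @param design optional data.frame with columns `sample_id`, `group`,
#'   `sex`, `gestational_day` to attach as colData; when `NULL` the
#'   returned object carries placeholder covariates and the design is
#'   attached later with [readDesign()].
#' @return `readCounts` returns a [TranscriptExperiment-class] (with
#'   placeholder covariates when `design` is `NULL`); `writeCounts`
#'   invisibly returns `path`.
#' @examples
#' sim <- simulateCounts(simulationSpec(nGenes = 10, seed = 1))
#' tmp <- tempfile(fileext = ".tsv")
#' writeCounts(sim$experiment, tmp)
#' cnt <- readCounts(tmp, design = studyDesign(sim$experiment))
#' @export
readCounts <- function(path, design = NULL) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("counts file has an empty body: ", path)
    if (ncol(tab) < 3L ||
        !identical(names(tab)[1:2], c("transcript_id", "gene_symbol")))
        stop("counts header must start with transcript_id, gene_symbol")
    if (anyDuplicated(tab$transcript_id))
        stop("duplicate transcript_id in ", path)
    if (anyDuplicated(names(tab)[-(1:2)]))
        stop("duplicate sample id in counts header")
    body <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (!is.numeric(body) || any(!is.finite(body)) || any(body < 0) ||
        any(body != round(body)))
        stop("counts body must be finite non-negative integers")
    rownames(body) <- tab$transcript_id
    if (is.null(design))
        design <- data.frame(sample_id = colnames(body), group = "CON",
                             sex = "F", gestational_day = 1,
                             stringsAsFactors = FALSE)
    TranscriptExperiment(body, tab$gene_symbol, design)
}

#' @rdname readCounts
#' @param x a [TranscriptExperiment-class].
#' @param header optional character vector written as leading `#` comment
#'   lines.
#' @export
writeCounts <- function(x, path, header = NULL) {
    stopifnot(is(x, "TranscriptExperiment"))
    out <- data.frame(transcript_id = rownames(x),
                      gene_symbol = geneSymbols(x),
                      SummarizedExperiment::assay(x, "counts"),
                      check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(out, path, header)
}

#' Read and write the sample-metadata table
#'
#' The design TSV has columns `sample_id`, `group` (CON/MNR), `sex` (F/M)
#' and `gestational_day`. `readDesign` validates the metadata against a
#' count container and returns the container with covariates attached.
#'
#' @param path file path.
#' @param x a [TranscriptExperiment-class] whose columns the metadata must
#'   exactly cover.
#' @return `readDesign` returns `x` with colData replaced; `writeDesign`
#'   invisibly returns `path`.
#' @export
readDesign <- function(path, x) {
    stopifnot(is(x, "TranscriptExperiment"))
    d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "sex", "gestational_day")
    if (!all(need %in% names(d)))
        stop("design file must have columns ", paste(need, collapse = ", "))
    if (!all(d$group %in% c("CON", "MNR")))
        stop("unknown group level: ",
             paste(setdiff(d$group, c("CON", "MNR")), collapse = ", "))
    if (!all(d$sex %in% c("F", "M")))
        stop("unknown sex level: ",
             paste(setdiff(d$sex, c("F", "M")), collapse = ", "))
    if (!setequal(d$sample_id, colnames(x)) || nrow(d) != ncol(x))
        stop("design samples do not match count-matrix columns")
    TranscriptExperiment(SummarizedExperiment::assay(x, "counts"),
                         geneSymbols(x), d)
}

#' @rdname readDesign
#' @param design data.frame as returned by [studyDesign()].
#' @param header optional `#` comment lines.
#' @export
writeDesign <- function(design, path, header = NULL) {
    .writeTsv(design, path, header)
}

#' Read a gene-interaction edge list
#'
#' Expects a TSV with columns `gene_a`, `gene_b` and optionally `score`
#' (confidence in `[0, 1]`); self-loops and duplicate edges are dropped.
#' Edge scores are retained for optional filtering but ignored for
#' topology, matching default MCODE behaviour.
#'
#' @param path file path.
#' @param minScore drop edges with `score` below this value (kept at 0 by
#'   default so unscored lists pass through unchanged).
#' @return data.frame `gene_a`, `gene_b`, `score`, deduplicated.
#' @export
readEdgeList <- function(path, minScore = 0) {
    d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% names(d)))
        stop("edge list must have columns gene_a, gene_b")
    if (is.null(d$score)) d$score <- 1
    if (any(!is.finite(d$score)) || any(d$score < 0 | d$score > 1))
        stop("edge scores must lie in [0, 1]")
    d <- d[d$score >= minScore & d$gene_a != d$gene_b, , drop = FALSE]
    key <- paste(pmin(d$gene_a, d$gene_b), pmax(d$gene_a, d$gene_b))
    d <- d[!duplicated(key), c("gene_a", "gene_b", "score")]
    rownames(d) <- NULL
    d
}

.writeTsv <- function(d, path, header = NULL) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "#", stringsAsFactors = FALSE)
}
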