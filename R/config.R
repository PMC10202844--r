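#' Create a pipeline configuration
#'
#' @param ... named overrides of [PipelineConfig-class] slots
#'   (`minMaxCount`, `presenceThreshold`, `fdrPrimary`, `pNetwork`,
#'   `fdrSplice`, `metaTimepoints`, `mcodeVwp`, `mcodeMinScore`,
#'   `mcodeMinNodes`, `mcodeHaircut`, `lowessSpan`, `rngSeed`).
#' @return A validated [PipelineConfig-class].
#' @examples
#' pipelineConfig(fdrPrimary = 0.05)
#' @export
pipelineConfig <- function(...) {
    args <- list(...)
    bad <- setdiff(names(args), slotNames("PipelineConfig"))
    if (length(bad))
        stop("unknown config fields: ", paste(bad, collapse = ", "))
    do.call(new, c(list("PipelineConfig"), args))
}

.configAsList <- function(config) {
    out <- lapply(slotNames("PipelineConfig"), function(nm) slot(config, nm))
    names(out) <- slotNames("PipelineConfig")
    out
}

#' Read and write flat key:value configuration files
#'
#' The on-disk format is one `key: value` pair per line; vectors are
#' comma-separated; `#` lines are comments.
#'
#' @param path file path.
#' @param config a [PipelineConfig-class].
#' @return `readConfig` returns a [PipelineConfig-class]; `writeConfig`
#'   invisibly returns `path`.
#' @export
readConfig <- function(path) {
    lines <- readLines(path)
    lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
    kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
    if (any(lengths(kv) != 3L))
        stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]])
    keys <- vapply(kv, `[`, "", 2L)
    vals <- lapply(kv, function(m) {
        v <- trimws(strsplit(m[3L], ",")[[1L]])
        if (all(v %in% c("TRUE", "FALSE"))) as.logical(v) else as.numeric(v)
    })
    do.call(pipelineConfig, setNames(vals, keys))
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
    stopifnot(is(config, "PipelineConfig"))
    vals <- .configAsList(config)
    lines <- vapply(names(vals), function(nm)
        sprintf("%s: %s", nm, paste(vals[[nm]], collapse = ",")), "")
    writeLines(lines, path)
    invisible(path)
}

.logStage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}
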