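#' Run the full analysis pipeline
#'
#' Executes filter, precision weighting, weighted fitting, moderation,
#' contrasts, FDR, gene deduplication and candidate selection; then the
#' splice-variant diversity pipeline on the unfiltered counts; then, when
#' an edge list is supplied, MCODE complex detection with the admission
#' rules. All stage outputs are written as TSV with a `#` comment header
#' recording the configuration snapshot and seed, together with a
#' `manifest.tsv` (input checksums, per-stage row counts) sufficient to
#' verify a byte-identical re-run.
#'
#' @param x a [TranscriptExperiment-class] of raw counts, or a
#'   [SimulationSpec-class] (the fixture is generated first and its truth
#'   table written alongside).
#' @param outdir output directory, created if needed.
#' @param edges optional edge-list data.frame for the network stage; when
#'   `NULL` the MCODE stage is skipped (and logged as skipped).
#' @param config a [PipelineConfig-class].
#' @return invisibly, a list with the in-memory results (`de`, `splice`,
#'   `mcode` or `NULL`) and the manifest data.frame.
#' @export
runAll <- function(x, outdir, edges = NULL, config = pipelineConfig()) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(sprintf("config %s", vapply(names(.configAsList(config)),
                 function(nm) sprintf("%s=%s", nm,
                     paste(.configAsList(config)[[nm]], collapse = ",")), "")),
             "time encoding: t = (gestational_day - 127.5) / 37.5",
             "reference levels: group=CON, sex=F")
    if (is(x, "SimulationSpec")) {
        sim <- simulateCounts(x)
        .writeTsv(sim$truth$transcripts, file.path(outdir, "truth_transcripts.tsv"))
        .writeTsv(sim$truth$genes, file.path(outdir, "truth_genes.tsv"))
        x <- sim$experiment
    }
    stopifnot(is(x, "TranscriptExperiment"))
    writeCounts(x, file.path(outdir, "counts.tsv"), header = hdr)
    writeDesign(studyDesign(x), file.path(outdir, "design.tsv"), header = hdr)

    de <- deAnalysis(x, config)
    for (nm in names(de$deduped))
        .writeTsv(de$deduped[[nm]],
                  file.path(outdir, sprintf("de_%s.tsv", nm)), header = hdr)
    combined <- do.call(rbind, lapply(names(de$deduped), function(nm)
        cbind(de$deduped[[nm]], contrast = nm)))
    combined <- combined[order(combined$p), ]
    .writeTsv(combined, file.path(outdir, "de_combined.tsv"), header = hdr)
    .writeTsv(de$candidates$primary, file.path(outdir, "candidates_primary.tsv"),
              header = hdr)
    .writeTsv(de$candidates$network, file.path(outdir, "candidates_network.tsv"),
              header = hdr)

    sp <- splicePipeline(x, config)
    for (d in names(sp@perTimepoint))
        .writeTsv(sp@perTimepoint[[d]],
                  file.path(outdir, sprintf("splice_tp%s.tsv", d)),
                  header = hdr)
    .writeTsv(sp@meta, file.path(outdir, "splice_meta.tsv"), header = hdr)
    g <- sp@global
    .writeTsv(data.frame(panel = c("all", "p_lt_0.05"),
                         n = c(g$n, g$subset05$n),
                         mean_z = c(g$mean, g$subset05$mean),
                         skewness = c(g$skewness, g$subset05$skewness),
                         t = c(g$t, g$subset05$t),
                         p = c(g$p, g$subset05$p)),
              file.path(outdir, "splice_global.tsv"), header = hdr)

    mc <- NULL
    if (!is.null(edges)) {
        bestFdr <- do.call(rbind, lapply(de$deduped, function(tab)
            tab[, c("gene_symbol", "fdr")]))
        mc <- mcodeComplexes(edges, bestFdr, config)
        flat <- mc
        flat$members <- vapply(mc$members, paste, "", collapse = ";")
        .writeTsv(flat, file.path(outdir, "mcode_complexes.tsv"), header = hdr)
    } else {
        .logStage("run-all", "no edge list supplied; MCODE stage skipped")
    }

    files <- sort(list.files(outdir, pattern = "\\.tsv$"))
    files <- setdiff(files, "manifest.tsv")
    manifest <- data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(outdir, files))),
        rows = vapply(files, function(f)
            nrow(.readTsv(file.path(outdir, f))), 0L),
        stringsAsFactors = FALSE)
    .writeTsv(manifest, file.path(outdir, "manifest.tsv"),
              header = c(hdr, sprintf("txsplice version %s",
                  as.character(utils::packageVersion("txsplice")))))
    invisible(list(de = de, splice = sp, mcode = mc, manifest = manifest))
}
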