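#' Create a simulation specification
#'
#' @param ... named overrides of [SimulationSpec-class] slots: `nGenes`,
#'   `isoLambda` (isoforms per gene are `1 + Poisson(isoLambda)`),
#'   `baselineMean`/`baselineSd` (log2 baseline abundance), `nbDispersion`,
#'   `fracDe`, `deEffect` (peak log2 group difference), `fracSplice`,
#'   `spliceEffect` (log increase of the expected expressed-isoform count),
#'   `affectedTimepoints`, `sexEffect`, `libSd` (sd of log-normal library
#'   factors), `design` (data.frame; defaults to [paperDesign()]), `seed`.
#' @return A validated [SimulationSpec-class].
#' @examples
#' simulationSpec(nGenes = 100, fracDe = 0, fracSplice = 0)
#' @export
simulationSpec <- function(...) {
    args <- list(...)
    bad <- setdiff(names(args), slotNames("SimulationSpec"))
    if (length(bad))
        stop("unknown simulation fields: ", paste(bad, collapse = ", "))
    do.call(new, c(list("SimulationSpec"), args))
}

.childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1000003 + 99991 * k) %% 2147483647)
}

## P(NB(mu, size = 1/phi) == 0) = (1 + phi * mu)^(-1/phi)
.nbPresenceProb <- function(mu, phi) 1 - (1 + phi * mu)^(-1 / phi)

#' Simulate transcript-level counts with injected effects
#'
#' Draws negative-binomial transcript counts for a two-group longitudinal
#' design. On the log2 scale the mean of transcript `i` in sample `j` is
#' `baseline_i + sexEffect * male_j + effect_i(dG_j) * MNR_j`, where the
#' injected group effect follows the quadratic profile
#' `effect(dG) = deEffect * -(dG - 90)(dG - 165) / 1406.25`: zero at the
#' design endpoints (90 and 165 dG) and maximal (`deEffect`) at
#' mid-gestation, dG = 127.5. Per-sample library factors are log-normal
#' with sd `libSd`. A disjoint set of splice-affected genes receives extra
#' low-abundance isoforms that are switched on only in MNR samples at the
#' affected timepoints, calibrated so the expected expressed-isoform count
#' rises by the factor `exp(spliceEffect)` there and is unchanged
#' elsewhere.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with `experiment` (a [TranscriptExperiment-class]),
#'   `truth` (list of data.frames `transcripts` and `genes` recording the
#'   injected status of every feature) and `spec`.
#' @examples
#' sim <- simulateCounts(simulationSpec(nGenes = 50, seed = 7))
#' table(sim$truth$genes$is_splice)
#' @export
simulateCounts <- function(spec) {
    stopifnot(is(spec, "SimulationSpec"))
    validObject(spec)
    design <- if (nrow(spec@design)) spec@design else paperDesign()
    nS <- nrow(design)
    male <- as.numeric(design$sex == "M")
    grp <- as.numeric(design$group == "MNR")
    dG <- design$gestational_day
    phi <- spec@nbDispersion

    ## structure: isoform counts, baselines, effect assignment
    set.seed(.childSeed(spec@seed, 1L))
    nIso <- 1L + stats::rpois(spec@nGenes, spec@isoLambda)
    genes <- sprintf("G%04d", seq_len(spec@nGenes))
    geneOf <- rep.int(genes, nIso)
    txIds <- paste0(geneOf, "_t", unlist(lapply(nIso, seq_len)))
    nT <- length(txIds)
    ## gene-level log2 abundance split across isoforms by flat-Dirichlet
    ## proportions, so minor isoforms sit near the presence boundary as in
    ## real transcript-level quantifications
    baselineGene <- stats::rnorm(spec@nGenes, spec@baselineMean,
                                 spec@baselineSd)
    prop <- unlist(lapply(nIso, function(k) {
        x <- stats::rexp(k)
        x / sum(x)
    }))
    baseline <- log2(prop) + rep.int(baselineGene, nIso)

    nDe <- round(spec@fracDe * spec@nGenes)
    nSp <- round(spec@fracSplice * spec@nGenes)
    if (nSp > 0 && all(nIso == 1L) && spec@spliceEffect > 0)
        stop("infeasible spec: splice effects need multi-isoform genes")
    pick <- sample(genes, nDe + nSp)
    deGenes <- pick[seq_len(nDe)]
    spGenes <- pick[nDe + seq_len(nSp)]
    isDe <- geneOf %in% deGenes

    ## quadratic profile: 0 at dG 90 and 165, peak 1 at dG 127.5
    quadProfile <- -(dG - 90) * (dG - 165) / 1406.25
    effect <- outer(ifelse(isDe, spec@deEffect, 0), quadProfile)

    set.seed(.childSeed(spec@seed, 2L))
    libFactor <- stats::rlnorm(nS, 0, spec@libSd)
    log2mu <- baseline +
        matrix(spec@sexEffect * male, nT, nS, byrow = TRUE) +
        sweep(effect, 2L, grp, `*`)
    mu <- sweep(2^log2mu, 2L, libFactor, `*`)
    counts <- matrix(stats::rnbinom(nT * nS, mu = mu, size = 1 / phi), nT, nS)

    ## splice-affected genes: activate extra isoforms in MNR at the
    ## affected timepoints so the expected expressed-isoform count rises
    ## by exp(spliceEffect)
    set.seed(.childSeed(spec@seed, 3L))
    affected <- grp == 1 & dG %in% spec@affectedTimepoints
    extraRows <- list(); extraIds <- character(); extraGene <- character()
    nExtraPerGene <- setNames(integer(length(genes)), genes)
    if (spec@spliceEffect > 0 && nSp > 0 && any(affected)) {
        for (g in spGenes) {
            rows <- which(geneOf == g)
            e0 <- mean(colSums(.nbPresenceProb(mu[rows, affected,
                                                  drop = FALSE], phi)))
            target <- e0 * (exp(spec@spliceEffect) - 1)
            nExtra <- max(1L, ceiling(target))
            pPres <- min(target / nExtra, 0.999)
            muExtra <- ((1 - pPres)^(-phi) - 1) / phi
            blk <- matrix(0L, nExtra, nS)
            blk[, affected] <- stats::rnbinom(nExtra * sum(affected),
                                              mu = muExtra, size = 1 / phi)
            extraRows[[g]] <- blk
            extraIds <- c(extraIds, paste0(g, "_x", seq_len(nExtra)))
            extraGene <- c(extraGene, rep(g, nExtra))
            nExtraPerGene[[g]] <- nExtra
        }
        counts <- rbind(counts, do.call(rbind, extraRows))
        txIds <- c(txIds, extraIds)
        geneOf <- c(geneOf, extraGene)
        isDe <- c(isDe, rep(FALSE, length(extraIds)))
    }
    rownames(counts) <- txIds
    colnames(counts) <- design$sample_id

    truthTx <- data.frame(transcript_id = txIds, gene_symbol = geneOf,
                          is_de = isDe,
                          de_effect = ifelse(isDe, spec@deEffect, 0),
                          stringsAsFactors = FALSE)
    truthGenes <- data.frame(gene_symbol = genes,
                             is_de = genes %in% deGenes,
                             is_splice = genes %in% spGenes,
                             splice_effect = ifelse(genes %in% spGenes,
                                                    spec@spliceEffect, 0),
                             n_isoforms_base = nIso,
                             n_isoforms_extra = as.integer(nExtraPerGene),
                             stringsAsFactors = FALSE)
    list(experiment = TranscriptExperiment(counts, geneOf, design),
         truth = list(transcripts = truthTx, genes = truthGenes),
         spec = spec)
}

#' Write a simulated fixture to disk
#'
#' Writes `counts.tsv`, `design.tsv`, `truth.tsv` (one row per gene plus
#' one per transcript) and a flat `spec.txt` snapshot from which the same
#' fixture can be regenerated byte-identically.
#'
#' @param spec a [SimulationSpec-class].
#' @param outdir writable directory (created if missing).
#' @return invisibly, the named character vector of file paths.
#' @export
writeFixture <- function(spec, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateCounts(spec)
    paths <- c(counts = file.path(outdir, "counts.tsv"),
               design = file.path(outdir, "design.tsv"),
               truth = file.path(outdir, "truth.tsv"),
               spec = file.path(outdir, "spec.txt"))
    writeCounts(sim$experiment, paths[["counts"]],
                header = sprintf("seed: %d", as.integer(spec@seed)))
    writeDesign(studyDesign(sim$experiment), paths[["design"]])
    tg <- sim$truth$genes
    tt <- sim$truth$transcripts
    truth <- rbind(
        data.frame(level = "gene", id = tg$gene_symbol,
                   gene_symbol = tg$gene_symbol, is_de = tg$is_de,
                   de_effect = NA_real_, is_splice = tg$is_splice,
                   splice_effect = tg$splice_effect,
                   stringsAsFactors = FALSE),
        data.frame(level = "transcript", id = tt$transcript_id,
                   gene_symbol = tt$gene_symbol, is_de = tt$is_de,
                   de_effect = tt$de_effect, is_splice = NA,
                   splice_effect = NA_real_, stringsAsFactors = FALSE))
    .writeTsv(truth, paths[["truth"]])
    writeSimulationSpec(spec, paths[["spec"]])
    invisible(paths)
}

#' Serialize and restore a simulation specification
#'
#' Scalar fields are stored one `key: value` per line (vectors
#' comma-separated); the design template travels separately as a design
#' TSV.
#'
#' @param spec a [SimulationSpec-class].
#' @param path file path of the snapshot.
#' @param designPath optional design TSV used as the design template.
#' @return `readSimulationSpec` returns a [SimulationSpec-class].
#' @export
writeSimulationSpec <- function(spec, path) {
    nms <- setdiff(slotNames("SimulationSpec"), "design")
    lines <- vapply(nms, function(nm)
        sprintf("%s: %s", nm, paste(slot(spec, nm), collapse = ",")), "")
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSimulationSpec
#' @export
readSimulationSpec <- function(path, designPath = NULL) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
    keys <- vapply(kv, `[`, "", 2L)
    vals <- lapply(kv, function(m)
        as.numeric(trimws(strsplit(m[3L], ",")[[1L]])))
    args <- setNames(vals, keys)
    if (!is.null(designPath)) args$design <- .readTsv(designPath)
    do.call(simulationSpec, args)
}
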