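#' Count expressed isoforms per gene and sample
#'
#' The splice-variant diversity outcome: for every gene and sample, the
#' number of distinct transcripts of that gene with at least
#' `presenceThreshold` reads. Counting is done on the unfiltered
#' transcript matrix so that low-abundance isoforms --- the plausible
#' carriers of a diversity effect --- are not pre-removed by the
#' expression filter.
#'
#' @param x a [TranscriptExperiment-class] (unfiltered).
#' @param presenceThreshold minimum reads for an isoform to count as
#'   expressed (default 1).
#' @return integer matrix, genes x samples, with gene symbols as rownames.
#' @examples
#' sim <- simulateCounts(simulationSpec(nGenes = 20, seed = 1))
#' iso <- countExpressedIsoforms(sim$experiment)
#' @export
countExpressedIsoforms <- function(x, presenceThreshold = 1) {
    stopifnot(is(x, "TranscriptExperiment"), presenceThreshold >= 1)
    present <- SummarizedExperiment::assay(x, "counts") >= presenceThreshold
    out <- rowsum(present + 0L, geneSymbols(x))
    storage.mode(out) <- "integer"
    out
}

#' Poisson regression of isoform counts on group, adjusting for sex
#'
#' Log-link Poisson GLM fitted by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 50 iterations) of a gene's
#' expressed-isoform counts at one timepoint on MNR status with sex as a
#' covariate. The returned effect is the log rate ratio MNR versus CON
#' with its Wald standard error from the inverse Fisher information.
#'
#' @param counts non-negative integer vector, one entry per sample.
#' @param group character/factor, `CON` or `MNR` per sample.
#' @param sex character/factor, `F` or `M` per sample.
#' @return list `beta`, `se`, `converged`. Fits that do not converge or
#'   drift to an unbounded estimate (e.g. a group with all-zero counts)
#'   are reported with `converged = FALSE`; all-identical positive counts
#'   are a valid zero-effect fit.
#' @export
poissonGlm <- function(counts, group, sex) {
    if (length(unique(group)) < 2L)
        stop("both groups must be present")
    X <- cbind(intercept = 1, MNR = as.numeric(group == "MNR"),
               sexM = as.numeric(sex == "M"))
    fit <- tryCatch(
        suppressWarnings(stats::glm.fit(X, counts, family = stats::poisson(),
            control = list(epsilon = 1e-8, maxit = 50L))),
        error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$boundary)
        return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
    beta <- fit$coefficients[["MNR"]]
    ## Fisher information from the IRLS working weights
    W <- fit$weights
    info <- crossprod(X * sqrt(W))
    V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(V))
        return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
    se <- sqrt(V[2L, 2L])
    if (!is.finite(beta) || !is.finite(se) || abs(beta) > 20 || se > 100)
        return(list(beta = NA_real_, se = NA_real_, converged = FALSE))
    list(beta = unname(beta), se = se, converged = TRUE)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-timepoint estimates with weights `w_i = SE_i^-2`:
#' `beta_hat = sum(w beta) / sum(w)`, `SE = 1 / sqrt(sum(w))`,
#' `Z = beta_hat / SE`, two-sided normal p-value.
#'
#' @param beta numeric vector of effect estimates.
#' @param se positive finite standard errors, same length.
#' @return list `beta`, `se`, `z`, `p`, `n` (number of studies combined).
#' @examples
#' inverseVarianceMeta(c(1, 1), c(1, 1))  # Z = sqrt(2)
#' @export
inverseVarianceMeta <- function(beta, se) {
    ok <- is.finite(beta) & is.finite(se) & se > 0
    beta <- beta[ok]; se <- se[ok]
    if (length(beta) == 0L)
        return(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, n = 0L))
    w <- se^-2
    b <- sum(w * beta) / sum(w)
    s <- sum(w)^-0.5
    z <- b / s
    list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)),
         n = length(beta))
}

#' Global distribution-shift test on meta Z-scores
#'
#' Summarizes whether the per-gene meta-analysis Z-scores are shifted away
#' from zero as a population: their mean, moment skewness
#' `g1 = m3 / m2^(3/2)`, and a two-sided one-sample t-test of mean zero.
#'
#' @param z numeric vector of at least 3 finite Z-scores with positive
#'   variance.
#' @return list `n`, `mean`, `skewness`, `t`, `p`.
#' @examples
#' globalShiftTest(c(-1, 0, 1))  # mean 0, skewness 0, p = 1
#' @export
globalShiftTest <- function(z) {
    z <- z[is.finite(z)]
    if (length(z) < 3L) stop("need at least 3 finite Z-scores")
    if (stats::var(z) == 0) stop("Z-scores have zero variance")
    m <- mean(z)
    m2 <- mean((z - m)^2); m3 <- mean((z - m)^3)
    tt <- stats::t.test(z, mu = 0)
    list(n = length(z), mean = m, skewness = m3 / m2^1.5,
         t = unname(tt$statistic), p = tt$p.value)
}

#' Splice-variant diversity pipeline
#'
#' Counts expressed isoforms on the unfiltered matrix, fits the Poisson
#' group regression per gene at every timepoint in the design (each
#' timepoint's gene list carries its own Benjamini-Hochberg FDR), combines
#' the configured meta timepoints per gene by fixed-effect
#' inverse-variance meta-analysis with FDR over the meta p-values, and
#' reports the global distribution-shift summary of all meta Z-scores and
#' of the subset with unadjusted p < 0.05. Genes whose regression fails at
#' one meta timepoint are still combined on the remaining one; genes
#' failing at all meta timepoints are excluded with a reason.
#'
#' @param x a [TranscriptExperiment-class] of raw (unfiltered) counts.
#' @param config a [PipelineConfig-class]; `metaTimepoints` must be
#'   present in the design.
#' @return A [SpliceMetaResult-class].
#' @export
splicePipeline <- function(x, config = pipelineConfig()) {
    design <- studyDesign(x)
    days <- sort(unique(design$gestational_day))
    if (!all(config@metaTimepoints %in% days))
        stop("meta timepoint(s) absent from design: ",
             paste(setdiff(config@metaTimepoints, days), collapse = ", "))
    iso <- countExpressedIsoforms(x, config@presenceThreshold)
    genes <- rownames(iso)

    perTp <- lapply(days, function(d) {
        sel <- design$gestational_day == d
        grp <- design$group[sel]; sex <- design$sex[sel]
        usable <- length(unique(grp)) == 2L
        fits <- if (usable)
            lapply(genes, function(g) poissonGlm(iso[g, sel], grp, sex))
        else
            rep(list(list(beta = NA_real_, se = NA_real_,
                          converged = FALSE)), length(genes))
        tab <- data.frame(
            gene_symbol = genes,
            beta = vapply(fits, `[[`, 0, "beta"),
            se = vapply(fits, `[[`, 0, "se"),
            converged = vapply(fits, `[[`, TRUE, "converged"),
            stringsAsFactors = FALSE)
        tab$p <- ifelse(tab$converged,
                        2 * stats::pnorm(-abs(tab$beta / tab$se)), NA_real_)
        tab$fdr <- NA_real_
        tab$fdr[tab$converged] <- bhFdr(tab$p[tab$converged])
        if (!usable)
            attr(tab, "unusable") <- "only one group present at this timepoint"
        tab
    })
    names(perTp) <- as.character(days)
    .logStage("splice", "%d genes x %d timepoints; meta over %s",
              length(genes), length(days),
              paste(config@metaTimepoints, collapse = "/"))

    metaTabs <- perTp[as.character(config@metaTimepoints)]
    metaRows <- lapply(seq_along(genes), function(i) {
        b <- vapply(metaTabs, function(tab) tab$beta[i], 0)
        s <- vapply(metaTabs, function(tab) tab$se[i], 0)
        inverseVarianceMeta(b, s)
    })
    nStud <- vapply(metaRows, `[[`, 0L, "n")
    meta <- data.frame(
        gene_symbol = genes,
        beta = vapply(metaRows, `[[`, 0, "beta"),
        se = vapply(metaRows, `[[`, 0, "se"),
        z = vapply(metaRows, `[[`, 0, "z"),
        p = vapply(metaRows, `[[`, 0, "p"),
        n_studies = nStud, stringsAsFactors = FALSE)
    excluded <- data.frame(
        gene_symbol = genes[nStud == 0L],
        reason = rep("regression failed at every meta timepoint",
                     sum(nStud == 0L)),
        stringsAsFactors = FALSE)
    meta <- meta[nStud > 0L, , drop = FALSE]
    meta$fdr <- bhFdr(meta$p)
    rownames(meta) <- NULL

    global <- globalShiftTest(meta$z)
    sub <- meta$z[meta$p < 0.05]
    global$subset05 <- if (length(sub) >= 3L && stats::var(sub) > 0)
        globalShiftTest(sub)
    else list(n = length(sub), mean = NA_real_, skewness = NA_real_,
              t = NA_real_, p = NA_real_)
    new("SpliceMetaResult", perTimepoint = perTp, meta = meta,
        global = global, excluded = excluded)
}
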