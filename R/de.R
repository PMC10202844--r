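#' Remove transcripts never rising above a count threshold
#'
#' Retains exactly the transcripts whose maximum raw count across all
#' samples is at least `minMaxCount`; low-count transcripts destabilize
#' the mean-variance trend the precision weights are estimated from.
#'
#' @param x a [TranscriptExperiment-class].
#' @param minMaxCount threshold; a transcript is removed when its maximum
#'   count is strictly below it (default 15).
#' @return the filtered [TranscriptExperiment-class]; warns (not errors)
#'   when nothing survives.
#' @examples
#' sim <- simulateCounts(simulationSpec(nGenes = 30, seed = 1))
#' filterLowCounts(sim$experiment)
#' @export
filterLowCounts <- function(x, minMaxCount = 15) {
    stopifnot(is(x, "TranscriptExperiment"), minMaxCount >= 1)
    keep <- apply(SummarizedExperiment::assay(x, "counts"), 1L, max) >=
        minMaxCount
    .logStage("filter", "retained %d / %d transcripts (max count >= %g)",
              sum(keep), nrow(x), minMaxCount)
    if (!any(keep)) warning("no transcripts pass the count filter")
    x[keep, ]
}

#' Observation-level precision weights from the mean-variance trend
#'
#' Computes `log2((count + 0.5) / (libsize + 1) * 1e6)`, fits each
#' transcript by ordinary least squares on the study model matrix, and
#' smooths the square-root residual standard deviations against average
#' log2 count with lowess. Each observation's fitted log2 count is mapped
#' through the interpolated trend and its precision weight is the fourth
#' power of the reciprocal predicted square-root standard deviation;
#' predictions are clipped to the fitted range at the extremes.
#'
#' @param x a filtered [TranscriptExperiment-class].
#' @param design model matrix (defaults to [buildModelMatrix()] on the
#'   sample covariates of `x`).
#' @param span lowess span for the trend fit.
#' @return A [WeightedExpression-class].
#' @export
voomWeights <- function(x, design = buildModelMatrix(x), span = 0.5) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    n <- ncol(cnt); p <- ncol(design)
    if (n < p) stop("fewer samples than model columns")
    if (n - p < 2L) stop("at least 2 residual degrees of freedom required")
    lib <- colSums(cnt)
    logcpm <- t(log2((t(cnt) + 0.5) / (lib + 1) * 1e6))
    fit <- stats::lm.fit(design, t(logcpm))
    res <- as.matrix(fit$residuals)
    sigma <- sqrt(colSums(res^2) / (n - p))
    ## trend: sqrt-sd versus average log2 count
    meanLogCount <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
    lo <- stats::lowess(meanLogCount, sqrt(sigma), f = span)
    trendFun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    fittedLogCpm <- t(design %*% fit$coefficients)
    fittedCount <- 1e-6 * sweep(2^fittedLogCpm, 2L, lib + 1, `*`)
    w <- trendFun(log2(fittedCount))^-4
    dim(w) <- dim(logcpm); dimnames(w) <- dimnames(logcpm)
    .logStage("voom", "%d transcripts x %d samples; weight range [%.3g, %.3g]",
              nrow(logcpm), n, min(w), max(w))
    new("WeightedExpression", logcpm = logcpm, weights = w,
        libSizes = lib, trend = list(x = lo$x, y = lo$y),
        geneSymbols = geneSymbols(x))
}

#' Per-transcript weighted least squares
#'
#' Fits `beta = (X'WX)^-1 X'Wy` per transcript with the observation
#' weights of a [WeightedExpression-class]; residual variance is the
#' weighted residual sum of squares over `n - p`, and unscaled coefficient
#' standard deviations come from the diagonal of `(X'WX)^-1`.
#'
#' @param expr a [WeightedExpression-class].
#' @param design full-rank model matrix.
#' @return A [WeightedLMFit-class]; transcripts with numerically singular
#'   normal equations are flagged and excluded downstream.
#' @export
fitWeightedLM <- function(expr, design) {
    stopifnot(is(expr, "WeightedExpression"))
    y <- expr@logcpm; w <- expr@weights
    n <- ncol(y); p <- ncol(design)
    if (qr(design)$rank < p) stop("model matrix is not full rank")
    nT <- nrow(y)
    beta <- matrix(NA_real_, nT, p, dimnames = list(rownames(y),
                                                    colnames(design)))
    stdev <- beta
    sigma2 <- rep(NA_real_, nT)
    flagged <- rep(FALSE, nT)
    for (i in seq_len(nT)) {
        wi <- w[i, ]; yi <- y[i, ]
        Xw <- design * sqrt(wi)
        ok <- TRUE
        R <- tryCatch(chol(crossprod(Xw)), error = function(e) NULL)
        if (is.null(R)) { flagged[i] <- TRUE; next }
        V <- chol2inv(R)
        b <- drop(V %*% crossprod(design, wi * yi))
        r <- yi - drop(design %*% b)
        beta[i, ] <- b
        stdev[i, ] <- sqrt(diag(V))
        sigma2[i] <- sum(wi * r^2) / (n - p)
    }
    new("WeightedLMFit", coefficients = beta, stdevUnscaled = stdev,
        sigma2 = sigma2, df = n - p, flagged = flagged,
        geneSymbols = expr@geneSymbols)
}

## Newton solve of trigamma(x) = y, vectorized (monotone decreasing map)
.trigammaInverse <- function(y) {
    x <- 0.5 + 1 / y
    for (iter in 1:50) {
        tri <- trigamma(x)
        dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
        x <- x + dif
        if (max(abs(dif / x)) < 1e-8) break
    }
    x
}

## moment matching of log residual variances to a scaled F distribution
.fitFDistMoments <- function(s2, df) {
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s02 <- exp(emean)
    }
    list(priorDf = d0, priorVar = s02)
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-transcript residual variances towards a common prior:
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`, with the prior degrees of
#' freedom `d0` and prior variance `s0^2` estimated by matching the
#' moments of `log s^2` to a scaled F distribution through
#' digamma/trigamma equations. Moderated t statistics gain `d0` degrees of
#' freedom. With `priorDf = 0` the moderated and ordinary statistics
#' coincide; when all variances are identical the prior degrees of freedom
#' are flagged infinite and every variance equals the prior.
#'
#' @param fit a [WeightedLMFit-class] (>= 10 finite residual variances).
#' @param priorDf optional fixed prior degrees of freedom overriding the
#'   moment estimate (0 disables moderation; `Inf` forces complete
#'   shrinkage, with the prior variance then estimated as the geometric
#'   mean consistent point).
#' @return list with `priorDf`, `priorVar`, per-transcript `sTilde` and
#'   `totalDf`, and logical `floored` marking zero-variance transcripts
#'   floored to the smallest positive variance.
#' @export
ebayesModerate <- function(fit, priorDf = NULL) {
    stopifnot(is(fit, "WeightedLMFit"))
    s2 <- fit@sigma2
    usable <- !fit@flagged & is.finite(s2)
    if (sum(usable) < 10L)
        stop("need >= 10 transcripts with finite residual variance")
    floored <- usable & s2 <= 0
    if (any(floored)) {
        s2[floored] <- min(s2[usable & s2 > 0])
        .logStage("ebayes", "floored %d zero-variance transcripts",
                  sum(floored))
    }
    if (is.null(priorDf)) {
        if (stats::var(log(s2[usable])) < 1e-15) {
            pr <- list(priorDf = Inf, priorVar = mean(s2[usable]))
        } else {
            pr <- .fitFDistMoments(s2[usable], fit@df)
        }
    } else {
        pv <- if (priorDf > 0) .fitFDistMoments(s2[usable], fit@df)$priorVar
              else NA_real_
        pr <- list(priorDf = priorDf, priorVar = pv)
    }
    d0 <- pr$priorDf; s02 <- pr$priorVar; d <- fit@df
    sTilde2 <- if (is.infinite(d0)) rep(s02, length(s2))
               else if (d0 == 0) s2
               else (d0 * s02 + d * s2) / (d0 + d)
    list(priorDf = d0, priorVar = s02, sTilde = sqrt(sTilde2),
         totalDf = d + d0, floored = floored)
}

#' Moderated contrast tests for the group terms
#'
#' Tests the three primary contrasts --- the MNR main effect and the
#' linear and quadratic group-by-time interactions --- with moderated t
#' statistics `beta_c / (u_c s_tilde)` on `d + d0` degrees of freedom, and
#' adjusts p-values with the Benjamini-Hochberg step-up within each
#' contrast separately.
#'
#' @param fit a [WeightedLMFit-class].
#' @param moderation output of [ebayesModerate()] (computed here when
#'   `NULL`).
#' @param contrasts named integer vector of coefficient indices to test.
#' @return A [DEResult-class].
#' @export
computeContrasts <- function(fit, moderation = NULL,
                             contrasts = c(MNR = 5L, MNR.t = 6L,
                                           MNR.t2 = 7L)) {
    stopifnot(is(fit, "WeightedLMFit"))
    if (is.null(moderation)) moderation <- ebayesModerate(fit)
    keep <- !fit@flagged
    dfTotal <- moderation$totalDf
    tabs <- lapply(names(contrasts), function(nm) {
        ci <- contrasts[[nm]]
        b <- fit@coefficients[keep, ci]
        u <- fit@stdevUnscaled[keep, ci]
        tmod <- b / (u * moderation$sTilde[keep])
        pval <- 2 * stats::pt(-abs(tmod), df = dfTotal)
        data.frame(transcript_id = rownames(fit@coefficients)[keep],
                   gene_symbol = fit@geneSymbols[keep],
                   coef = b, t_mod = tmod, p = pval, fdr = bhFdr(pval),
                   row.names = NULL, stringsAsFactors = FALSE)
    })
    names(tabs) <- names(contrasts)
    new("DEResult", contrasts = tabs, priorDf = moderation$priorDf,
        priorVar = moderation$priorVar, sTilde = moderation$sTilde,
        fit = fit)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} m p_(j) / j` capped at 1,
#' returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` is an error.
#' @return adjusted p-values, same length and order.
#' @export
bhFdr <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (any(is.na(p))) stop("NA p-values are not allowed")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Collapse transcripts to one row per gene symbol
#'
#' After multiplicity correction, transcripts sharing a gene symbol are
#' reduced to the most significant one (minimum p; ties broken by larger
#' absolute moderated t, then lexicographic transcript id).
#'
#' @param table data.frame with columns `gene_symbol`, `p` and optionally
#'   `t_mod`, `transcript_id`.
#' @return the deduplicated table, one row per gene symbol.
#' @export
dedupeGeneSymbols <- function(table) {
    stopifnot(all(c("gene_symbol", "p") %in% names(table)))
    tmod <- if ("t_mod" %in% names(table)) abs(table$t_mod) else
        rep(0, nrow(table))
    txid <- if ("transcript_id" %in% names(table)) table$transcript_id else
        as.character(seq_len(nrow(table)))
    ord <- order(table$gene_symbol, table$p, -tmod, txid)
    tab <- table[ord, , drop = FALSE]
    out <- tab[!duplicated(tab$gene_symbol), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Select candidate genes from the deduplicated contrast tables
#'
#' The primary set holds genes reaching FDR < `fdrPrimary` in any of the
#' three contrasts; the network set holds genes with unadjusted
#' p < `pNetwork` in any contrast (the looser admission used to seed the
#' interaction-network analysis). Both are reported with their qualifying
#' contrast; neither set is required to contain the other.
#'
#' @param tables named list of deduplicated contrast tables (see
#'   [dedupeGeneSymbols()]).
#' @param config a [PipelineConfig-class].
#' @return list of data.frames `primary` and `network`, each with
#'   `gene_symbol`, `contrast`, `p`, `fdr`.
#' @export
selectCandidates <- function(tables, config = pipelineConfig()) {
    gather <- function(cond) {
        hits <- lapply(names(tables), function(nm) {
            tab <- tables[[nm]]
            sel <- cond(tab)
            if (!any(sel)) return(NULL)
            data.frame(gene_symbol = tab$gene_symbol[sel], contrast = nm,
                       p = tab$p[sel], fdr = tab$fdr[sel],
                       stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, hits)
        if (is.null(out))
            return(data.frame(gene_symbol = character(),
                              contrast = character(), p = numeric(),
                              fdr = numeric(), stringsAsFactors = FALSE))
        out <- out[order(out$p), , drop = FALSE]
        rownames(out) <- NULL
        out
    }
    list(primary = gather(function(tab) tab$fdr < config@fdrPrimary),
         network = gather(function(tab) tab$p < config@pNetwork))
}

#' Full differential-expression stage
#'
#' Convenience wrapper chaining [filterLowCounts()], [voomWeights()],
#' [fitWeightedLM()], [ebayesModerate()], [computeContrasts()],
#' [dedupeGeneSymbols()] and [selectCandidates()].
#'
#' @param x a [TranscriptExperiment-class] of raw counts.
#' @param config a [PipelineConfig-class].
#' @return list with `result` (a [DEResult-class]), `deduped` (named list
#'   of per-contrast gene-level tables) and `candidates` (see
#'   [selectCandidates()]).
#' @export
deAnalysis <- function(x, config = pipelineConfig()) {
    filt <- filterLowCounts(x, config@minMaxCount)
    design <- buildModelMatrix(filt)
    expr <- voomWeights(filt, design, span = config@lowessSpan)
    fit <- fitWeightedLM(expr, design)
    res <- computeContrasts(fit)
    deduped <- lapply(res@contrasts, dedupeGeneSymbols)
    list(result = res, deduped = deduped,
         candidates = selectCandidates(deduped, config))
}
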