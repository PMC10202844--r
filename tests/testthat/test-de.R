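test_that("the count filter keeps exactly transcripts reaching the threshold", {
    cnt <- rbind(rep(14L, 8),              # never reaches 15 -> removed
                 c(15L, rep(0L, 7)),       # one sample at 15 -> retained
                 rep(100L, 8))
    x <- tinyExperiment(cnt)
    suppressMessages(f <- filterLowCounts(x, 15))
    expect_identical(rownames(f), c("tx02", "tx03"))
    # brute-force row-max oracle on a random matrix
    set.seed(71)
    cnt <- matrix(rpois(1000, 8), 100, 10)
    x <- tinyExperiment(cnt)
    suppressMessages(f <- filterLowCounts(x, 15))
    expect_identical(rownames(f),
                     rownames(x)[apply(cnt, 1, max) >= 15])
    suppressMessages(expect_warning(filterLowCounts(x, 1e6), "no transcripts"))
})

test_that("precision weights are positive, finite, and track abundance", {
    sim <- simulateCounts(simulationSpec(nGenes = 300, seed = 8))
    filt <- suppressMessages(filterLowCounts(sim$experiment))
    X <- buildModelMatrix(filt)
    expr <- suppressMessages(voomWeights(filt, X))
    expect_true(all(is.finite(expr@weights)) && all(expr@weights > 0))
    expect_true(all(is.finite(expr@logcpm)))
    # under NB noise the lower-abundance half gets lower median weight
    ab <- rowMeans(expr@logcpm)
    lowHalf <- ab < median(ab)
    expect_lt(median(expr@weights[lowHalf, ]),
              median(expr@weights[!lowHalf, ]))
})

test_that("near-constant-variance data yields a near-flat weight surface", {
    # matched means and vanishing dispersion: counts are Poisson at a single
    # abundance, so the fitted trend has nothing to vary over
    spec <- simulationSpec(nGenes = 400, isoLambda = 0, baselineMean = 8,
                           baselineSd = 0, nbDispersion = 1e-4, fracDe = 0,
                           fracSplice = 0, sexEffect = 0, libSd = 1e-9,
                           seed = 13)
    sim <- simulateCounts(spec)
    filt <- suppressMessages(filterLowCounts(sim$experiment))
    expr <- suppressMessages(voomWeights(filt, buildModelMatrix(filt)))
    cv <- sd(expr@weights) / mean(expr@weights)
    expect_lt(cv, 0.2)
})

test_that("weighted least squares matches oracles on identity and random weights", {
    set.seed(5)
    d <- paperDesign()[1:12, ]
    X <- cbind(intercept = 1, x1 = rnorm(12), x2 = rnorm(12))
    y <- rnorm(12)
    mkExpr <- function(y, w) new("WeightedExpression",
        logcpm = matrix(y, 1, 12, dimnames = list("t1", d$sample_id)),
        weights = matrix(w, 1, 12), libSizes = rep(1e6, 12),
        trend = list(x = 0, y = 1), geneSymbols = "g1")
    # unit weights equal ordinary least squares
    fit <- fitWeightedLM(mkExpr(y, rep(1, 12)), X)
    ols <- lm.fit(X, y)
    expect_equal(unname(fit@coefficients[1, ]), unname(ols$coefficients),
                 tolerance = 1e-10)
    # duplicated sample at half weight equals the single sample at weight 1
    X2 <- rbind(X, X[12, ])
    y2 <- c(y, y[12])
    w2 <- c(rep(1, 11), 0.5, 0.5)
    d2 <- rbind(d, transform(d[12, ], sample_id = "s99"))
    expr2 <- new("WeightedExpression",
        logcpm = matrix(y2, 1, 13, dimnames = list("t1", d2$sample_id)),
        weights = matrix(w2, 1, 13), libSizes = rep(1e6, 13),
        trend = list(x = 0, y = 1), geneSymbols = "g1")
    fit2 <- fitWeightedLM(expr2, X2)
    expect_equal(fit2@coefficients[1, ], fit@coefficients[1, ],
                 tolerance = 1e-10)
    # random instances against direct normal equations
    for (rep in 1:20) {
        w <- runif(12, 0.2, 5)
        y <- rnorm(12)
        fit <- fitWeightedLM(mkExpr(y, w), X)
        orc <- oracleWLS(X, y, w)
        expect_equal(unname(fit@coefficients[1, ]), unname(orc$beta),
                     tolerance = 1e-8)
        expect_equal(fit@sigma2[1], orc$sigma2, tolerance = 1e-8)
        expect_equal(unname(fit@stdevUnscaled[1, ]), unname(orc$stdev),
                     tolerance = 1e-8)
    }
})

test_that("moderation shrinks variances and collapses to ordinary t at zero prior df", {
    sim <- simulateCounts(simulationSpec(nGenes = 120, seed = 17))
    filt <- suppressMessages(filterLowCounts(sim$experiment))
    X <- buildModelMatrix(filt)
    expr <- suppressMessages(voomWeights(filt, X))
    fit <- fitWeightedLM(expr, X)
    # d0 = 0: moderated t equals the ordinary WLS t statistic
    res0 <- computeContrasts(fit, ebayesModerate(fit, priorDf = 0))
    tOrd <- fit@coefficients[, 5] / (fit@stdevUnscaled[, 5] * sqrt(fit@sigma2))
    expect_equal(deTable(res0, "MNR")$t_mod, unname(tOrd), tolerance = 1e-12)
    # monotonicity: at fixed beta and covariance, larger s2 gives smaller |t|
    mod <- ebayesModerate(fit)
    ord <- order(fit@sigma2)
    tAt <- abs(fit@coefficients[ord[1], 5]) /
        (fit@stdevUnscaled[ord[1], 5] * mod$sTilde[ord])
    expect_true(all(diff(tAt) <= 1e-12))
})

test_that("moderated statistics agree with the limma reference route", {
    skip_if_not_installed("limma")
    sim <- simulateCounts(simulationSpec(nGenes = 250, seed = 23))
    filt <- suppressMessages(filterLowCounts(sim$experiment))
    X <- buildModelMatrix(filt)
    expr <- suppressMessages(voomWeights(filt, X))
    fit <- fitWeightedLM(expr, X)
    res <- computeContrasts(fit)
    v <- limma::voom(SummarizedExperiment::assay(filt), X)
    lf <- limma::eBayes(limma::lmFit(v, X))
    expect_equal(priorDf(res), lf$df.prior, tolerance = 1e-6)
    expect_equal(priorVar(res), lf$s2.prior, tolerance = 1e-6)
    expect_equal(deTable(res, "MNR.t2")$t_mod, unname(lf$t[, 7]),
                 tolerance = 1e-6)
    expect_equal(deTable(res, "MNR.t2")$p, unname(lf$p.value[, 7]),
                 tolerance = 1e-6)
})

test_that("BH adjustment matches its step-up definition", {
    expect_equal(bhFdr(0.03), 0.03)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(41)
    for (rep in 1:20) {
        p <- runif(sample(1:50, 1))
        q <- bhFdr(p)
        expect_equal(q, oracleBH(p), tolerance = 1e-12)
        expect_true(all(q >= p - 1e-15))
        expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
    expect_error(bhFdr(c(0.1, NA)), "NA")
    expect_error(bhFdr(1.3), "0, 1")
})

test_that("gene deduplication keeps the most significant transcript", {
    tab <- data.frame(transcript_id = c("t1", "t2", "t3"),
                      gene_symbol = c("g", "g", "h"),
                      t_mod = c(1, 4, 2), p = c(0.5, 0.01, 0.2))
    out <- dedupeGeneSymbols(tab)
    expect_identical(out$transcript_id[out$gene_symbol == "g"], "t2")
    # all-unique symbols pass through
    tab$gene_symbol <- c("a", "b", "c")
    expect_equal(nrow(dedupeGeneSymbols(tab)), 3L)
    # random tables against the group-by oracle (incl. tied p)
    set.seed(91)
    for (rep in 1:10) {
        n <- 60
        tab <- data.frame(
            transcript_id = sprintf("t%03d", sample(n)),
            gene_symbol = sample(letters[1:12], n, replace = TRUE),
            t_mod = rnorm(n),
            p = round(runif(n), 2))  # rounding forces ties
        out <- dedupeGeneSymbols(tab)
        orc <- oracleDedupe(tab)
        out <- out[order(out$gene_symbol), ]
        orc <- orc[order(orc$gene_symbol), ]
        expect_equal(out$transcript_id, orc$transcript_id)
    }
})

test_that("candidate selection applies the two admission rules separately", {
    tabs <- list(
        MNR = data.frame(gene_symbol = c("a", "b"), p = c(0.0001, 0.5),
                         fdr = c(0.09, 0.9), t_mod = 1:2,
                         transcript_id = c("t1", "t2")),
        MNR.t = data.frame(gene_symbol = c("a", "b"), p = c(0.9, 0.9),
                           fdr = c(0.9, 0.9), t_mod = 1:2,
                           transcript_id = c("t1", "t2")),
        MNR.t2 = data.frame(gene_symbol = c("a", "b"), p = c(0.9, 0.0009),
                            fdr = c(0.9, 0.14), t_mod = 1:2,
                            transcript_id = c("t1", "t2")))
    sel <- selectCandidates(tabs)
    # FDR 0.09 -> primary; p 0.0009 with FDR 0.14 -> network only
    expect_identical(sel$primary$gene_symbol, "a")
    expect_setequal(sel$network$gene_symbol, c("a", "b"))
    empty <- lapply(tabs, function(t) t[0, ])
    sel0 <- selectCandidates(empty)
    expect_equal(nrow(sel0$primary), 0L)
    expect_equal(nrow(sel0$network), 0L)
})

test_that("the DE pipeline is invariant to sample-column permutation", {
    sim <- simulateCounts(simulationSpec(nGenes = 120, seed = 33))
    x <- sim$experiment
    perm <- sample(ncol(x))
    de1 <- suppressMessages(deAnalysis(x))
    de2 <- suppressMessages(deAnalysis(x[, perm]))
    for (nm in c("MNR", "MNR.t", "MNR.t2"))
        expect_equal(deTable(de2$result, nm)$p, deTable(de1$result, nm)$p,
                     tolerance = 1e-10)
})
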