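test_that("expressed-isoform counting matches its definition and oracle", {
    cnt <- rbind(c(5L, 0L), c(0L, 0L), c(2L, 0L))
    x <- tinyExperiment(cnt, genes = c("g", "g", "g"))
    iso <- countExpressedIsoforms(x, 1)
    expect_equal(unname(iso["g", ]), c(2L, 0L))
    # threshold respects >= semantics
    expect_equal(unname(countExpressedIsoforms(x, 2)["g", ]), c(2L, 0L))
    expect_equal(unname(countExpressedIsoforms(x, 3)["g", ]), c(1L, 0L))
    # random matrix against per-gene brute force
    set.seed(55)
    cnt <- matrix(rpois(600, 1.5), 60, 10)
    genes <- sample(sprintf("g%02d", 1:15), 60, replace = TRUE)
    x <- tinyExperiment(cnt, genes = genes)
    expect_identical(countExpressedIsoforms(x, 2),
                     oracleIsoCount(SummarizedExperiment::assay(x),
                                    genes, 2))
})

test_that("the Poisson group regression recovers closed-form balanced effects", {
    grp <- rep(c("CON", "MNR"), each = 8)
    sex <- rep(c("F", "M"), 8)
    # identical counts in both groups, sexes balanced: zero effect
    fit <- poissonGlm(rep(3L, 16), grp, sex)
    expect_true(fit$converged)
    expect_equal(fit$beta, 0, tolerance = 1e-10)
    # balanced two-group data: beta = log of the group mean ratio
    counts <- c(rep(2L, 8), rep(5L, 8))
    fit <- poissonGlm(counts, grp, sex)
    expect_equal(fit$beta, log(5 / 2), tolerance = 1e-8)
    # Wald SE for saturated-in-group balanced design: sqrt(1/sum1 + 1/sum2)
    expect_equal(fit$se, sqrt(1 / 16 + 1 / 40), tolerance = 1e-6)
    # a group with all-zero counts is an unbounded estimate
    fit <- poissonGlm(c(rep(0L, 8), rep(4L, 8)), grp, sex)
    expect_false(fit$converged)
    expect_error(poissonGlm(1:4, rep("CON", 4), rep("F", 4)), "both groups")
})

test_that("the Poisson regression is calibrated on simulated GLM data", {
    set.seed(61)
    n <- 200
    grp <- rep(c("CON", "MNR"), each = n / 2)
    sex <- rep(c("F", "M"), n / 2)
    betaTrue <- 0.4
    within3 <- replicate(500, {
        mu <- exp(1 + betaTrue * (grp == "MNR") + 0.1 * (sex == "M"))
        fit <- poissonGlm(rpois(n, mu), grp, sex)
        fit$converged && abs(fit$beta - betaTrue) < 3 * fit$se
    })
    expect_gte(mean(within3), 0.99)
})

test_that("inverse-variance combination satisfies its identities and oracle", {
    one <- inverseVarianceMeta(1.0, 0.5)
    expect_equal(one$beta, 1.0)
    expect_equal(one$z, 2.0)
    pair <- inverseVarianceMeta(c(1, 1), c(1, 1))
    expect_equal(pair$beta, 1)
    expect_equal(pair$se, 1 / sqrt(2))
    expect_equal(pair$z, sqrt(2))
    # identical effects and SEs across the two timepoints: meta Z is
    # sqrt(2) times the per-timepoint Z
    z1 <- 0.8 / 0.3
    expect_equal(inverseVarianceMeta(c(0.8, 0.8), c(0.3, 0.3))$z,
                 sqrt(2) * z1)
    set.seed(77)
    for (rep in 1:25) {
        k <- sample(1:6, 1)
        b <- rnorm(k); s <- runif(k, 0.1, 2)
        got <- inverseVarianceMeta(b, s)
        orc <- oracleMeta(b, s)
        expect_equal(got$beta, orc$beta, tolerance = 1e-12)
        expect_equal(got$se, orc$se, tolerance = 1e-12)
        expect_equal(got$z, orc$z, tolerance = 1e-12)
    }
    expect_equal(inverseVarianceMeta(numeric(), numeric())$n, 0L)
})

test_that("the combination agrees with the metafor fixed-effect reference", {
    skip_if_not_installed("metafor")
    set.seed(78)
    b <- rnorm(4); s <- runif(4, 0.2, 1)
    got <- inverseVarianceMeta(b, s)
    ref <- metafor::rma(yi = b, sei = s, method = "EE")
    expect_equal(got$beta, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(got$se, ref$se, tolerance = 1e-8)
})

test_that("the global shift test returns the documented summaries", {
    sym <- globalShiftTest(c(-1, 0, 1))
    expect_equal(sym$mean, 0)
    expect_equal(sym$skewness, 0)
    expect_equal(sym$p, 1)
    ramp <- globalShiftTest(c(1, 2, 3, 4, 5))
    expect_equal(ramp$mean, 3)
    expect_equal(ramp$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
    expect_equal(ramp$skewness, 0)
    expect_error(globalShiftTest(rep(2, 5)), "zero variance")
    expect_error(globalShiftTest(c(1, 2)), "at least 3")
})

test_that("swapping the group labels negates every effect and meta Z", {
    sim <- simulateCounts(simulationSpec(nGenes = 60, seed = 19))
    x <- sim$experiment
    d <- studyDesign(x)
    d$group <- ifelse(d$group == "CON", "MNR", "CON")
    y <- TranscriptExperiment(SummarizedExperiment::assay(x),
                              geneSymbols(x), d)
    spA <- suppressMessages(splicePipeline(x))
    spB <- suppressMessages(splicePipeline(y))
    mA <- spliceMeta(spA); mB <- spliceMeta(spB)
    expect_identical(mA$gene_symbol, mB$gene_symbol)
    expect_equal(mB$beta, -mA$beta, tolerance = 1e-6)
    expect_equal(mB$z, -mA$z, tolerance = 1e-6)
    tpA <- splicePerTimepoint(spA)[["120"]]
    tpB <- splicePerTimepoint(spB)[["120"]]
    ok <- tpA$converged & tpB$converged
    expect_equal(tpB$beta[ok], -tpA$beta[ok], tolerance = 1e-6)
})

test_that("genes failing one meta timepoint fall back to the other", {
    # gene g2 is silent at 120 dG (regression unbounded there) but active
    # at 140 dG: the meta must keep it with a single study
    d <- expand.grid(group = c("CON", "MNR"), sex = c("F", "M"),
                     gestational_day = c(120, 140), rep = 1:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$sample_id <- sprintf("s%02d", seq_len(nrow(d)))
    at120 <- d$gestational_day == 120
    set.seed(3)
    genes <- rep(sprintf("g%02d", 1:20), each = 2)
    cnt <- matrix(rpois(40 * nrow(d), 3), 40, nrow(d),
                  dimnames = list(paste0(genes, "_t", rep(1:2, 20)),
                                  d$sample_id))
    cnt[genes == "g02", at120] <- 0L
    x <- TranscriptExperiment(cnt, genes, d)
    sp <- suppressMessages(splicePipeline(x))
    m <- spliceMeta(sp)
    expect_true("g02" %in% m$gene_symbol)
    expect_equal(m$n_studies[m$gene_symbol == "g02"], 1L)
    expect_true(all(m$n_studies[m$gene_symbol != "g02"] %in% 1:2))
    # a configured timepoint absent from the design is a config error
    expect_error(
        splicePipeline(x, pipelineConfig(metaTimepoints = c(120, 165))),
        "absent")
})

test_that("per-gene FDR columns are BH over the converged fits", {
    sim <- simulateCounts(simulationSpec(nGenes = 40, seed = 29))
    sp <- suppressMessages(splicePipeline(sim$experiment))
    tp <- splicePerTimepoint(sp)[["140"]]
    ok <- tp$converged
    expect_equal(tp$fdr[ok], bhFdr(tp$p[ok]))
    expect_true(all(is.na(tp$fdr[!ok])))
    m <- spliceMeta(sp)
    expect_equal(m$fdr, bhFdr(m$p))
    expect_true(all(m$fdr >= m$p - 1e-15))
})
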