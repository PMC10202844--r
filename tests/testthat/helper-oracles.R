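## Independent brute-force oracles and tiny fixture builders used across
## the suite. All fixtures are generated in code; nothing is read from disk.

## tiny experiment with hand-chosen counts
tinyExperiment <- function(counts, genes = NULL, design = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("tx%02d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
    if (is.null(genes)) genes <- sub("^tx", "g", rownames(counts))
    if (is.null(design)) {
        n <- ncol(counts)
        design <- data.frame(sample_id = colnames(counts),
                             group = rep(c("CON", "MNR"), length.out = n),
                             sex = rep(c("F", "M"), each = ceiling(n / 2))[1:n],
                             gestational_day = 120,
                             stringsAsFactors = FALSE)
    }
    TranscriptExperiment(counts, genes, design)
}

## step-up BH by direct definition: q_(i) = min_{j>=i} m p_(j)/j
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- sapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))))
    out <- numeric(m)
    out[o] <- q
    out
}

## weighted least squares by direct normal equations with solve()
oracleWLS <- function(X, y, w) {
    XtWX <- t(X) %*% diag(w) %*% X
    beta <- solve(XtWX, t(X) %*% (w * y))
    r <- y - X %*% beta
    p <- ncol(X)
    list(beta = drop(beta),
         sigma2 = sum(w * r^2) / (length(y) - p),
         stdev = sqrt(diag(solve(XtWX))))
}

## group-by minimum-p per gene symbol with the documented tie-breaks
oracleDedupe <- function(tab) {
    do.call(rbind, lapply(split(tab, tab$gene_symbol), function(g) {
        g <- g[g$p == min(g$p), , drop = FALSE]
        if (nrow(g) > 1L) g <- g[abs(g$t_mod) == max(abs(g$t_mod)), ,
                                 drop = FALSE]
        g[order(g$transcript_id)[1L], , drop = FALSE]
    }))
}

## fixed-effect inverse-variance combination by the textbook formulas
oracleMeta <- function(beta, se) {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    list(beta = b, se = s, z = b / s)
}

## per-gene expressed-isoform counts by explicit double loop
oracleIsoCount <- function(counts, genes, threshold) {
    ug <- sort(unique(genes))
    out <- matrix(0L, length(ug), ncol(counts),
                  dimnames = list(ug, colnames(counts)))
    for (g in ug)
        for (j in seq_len(ncol(counts)))
            out[g, j] <- sum(counts[genes == g, j] >= threshold)
    out
}

## MCODE vertex weights by exhaustive subset enumeration (graphs <= ~12
## nodes): highest k over all induced subgraphs of the closed
## neighbourhood, then density of the union of all subsets attaining it
oracleMcodeWeights <- function(adj) {
    n <- nrow(adj)
    vapply(seq_len(n), function(v) {
        nb <- which(adj[v, ] > 0)
        if (length(nb) == 0L) return(0)
        vs <- sort(c(v, nb))
        A <- adj[vs, vs, drop = FALSE]
        m <- length(vs)
        subsets <- lapply(seq_len(2^m - 1), function(mask)
            which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1))) != 0L))
        subsets <- Filter(function(s) length(s) >= 2L, subsets)
        mindeg <- vapply(subsets, function(s)
            min(rowSums(A[s, s, drop = FALSE])), 0)
        k <- max(mindeg)
        if (k == 0) return(0)
        core <- sort(unique(unlist(subsets[mindeg >= k])))
        nc <- length(core)
        k * sum(A[core, core]) / (nc * (nc - 1))
    }, 0)
}

## random Erdos-Renyi adjacency matrix with vertex names
randomAdjacency <- function(n, prob) {
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < prob)
    adj <- adj + t(adj)
    dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
    adj
}

adjacencyToEdges <- function(adj) {
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    data.frame(gene_a = rownames(adj)[idx[, 1]],
               gene_b = colnames(adj)[idx[, 2]],
               stringsAsFactors = FALSE)
}

## complete graph on named vertices as an edge list
cliqueEdges <- function(names) {
    cmb <- t(combn(names, 2))
    data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2],
               stringsAsFactors = FALSE)
}
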