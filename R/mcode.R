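#' Build a simple gene-interaction graph
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (and optionally
#'   `score`), as returned by [readEdgeList()].
#' @return an undirected simple [igraph::igraph] (self-loops and duplicate
#'   edges collapsed); confidence scores are ignored for topology.
#' @export
geneGraph <- function(edges) {
    stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
    g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

.coreDensity <- function(sub) {
    ## highest k-core of a graph: k, its density and its vertex count
    if (igraph::gorder(sub) < 2L || igraph::gsize(sub) == 0L)
        return(list(k = 0, density = 0, n = igraph::gorder(sub)))
    core <- igraph::coreness(sub)
    k <- max(core)
    cs <- igraph::induced_subgraph(sub, which(core == k))
    n <- igraph::gorder(cs)
    dens <- if (n < 2L) 0 else 2 * igraph::gsize(cs) / (n * (n - 1))
    list(k = k, density = dens, n = n)
}

#' MCODE vertex weighting
#'
#' For every vertex, the induced subgraph on the vertex and its neighbours
#' (the closed neighbourhood) is reduced to its highest k-core; the vertex
#' weight is that core's `k` multiplied by the core's density
#' `2E / (n(n-1))`. Isolated vertices weigh 0.
#'
#' @param graph an undirected simple [igraph::igraph].
#' @return named numeric vector of weights, one per vertex.
#' @examples
#' g <- geneGraph(data.frame(gene_a = c("a","a","b","b","c","c","d","d","e","e")[1:10],
#'                           gene_b = c("b","c","c","d","d","e","e","a","a","b")[1:10]))
#' mcodeVertexWeights(g)  # K5: every vertex weighs 4
#' @export
mcodeVertexWeights <- function(graph) {
    vs <- igraph::V(graph)
    w <- vapply(seq_along(vs), function(i) {
        nb <- igraph::neighbors(graph, vs[i])
        if (length(nb) == 0L) return(0)
        sub <- igraph::induced_subgraph(graph, c(vs[i], nb))
        cd <- .coreDensity(sub)
        cd$k * cd$density
    }, 0)
    names(w) <- igraph::V(graph)$name
    w
}

#' MCODE molecular-complex prediction
#'
#' Greedy seeded expansion: the highest-weighted unassigned vertex seeds a
#' complex, which grows breadth-first over neighbours whose weight is at
#' least `seed weight * (1 - vwp)` (the vertex weight percentage). Members
#' of a kept complex are consumed and can join no other complex; failed
#' seeds remain available as members elsewhere. The optional haircut prunes
#' the complex to its 2-core, removing singly-connected members. Complexes
#' are scored `density * n` and returned sorted by score (descending),
#' with lexicographic tie-breaking on vertex names throughout, so the
#' output is deterministic.
#'
#' @param graph an undirected simple [igraph::igraph].
#' @param weights vertex weights from [mcodeVertexWeights()] (computed
#'   when `NULL`).
#' @param vwp vertex weight percentage in `[0, 1)` (default 0.2).
#' @param haircut prune each complex to its 2-core (default `TRUE`).
#' @return data.frame `complex_id`, `seed`, `n`, `density`, `score`, plus
#'   a `members` list-column of vertex names.
#' @export
mcodeFindComplexes <- function(graph, weights = NULL, vwp = 0.2,
                               haircut = TRUE) {
    stopifnot(vwp >= 0, vwp < 1)
    if (is.null(weights)) weights <- mcodeVertexWeights(graph)
    nms <- igraph::V(graph)$name
    weights <- weights[nms]
    order_ <- nms[order(-weights, nms)]
    assigned <- seeded <- setNames(rep(FALSE, length(nms)), nms)
    out <- list()
    for (seed in order_) {
        if (assigned[seed] || seeded[seed]) next
        seeded[seed] <- TRUE
        thr <- weights[seed] * (1 - vwp)
        members <- seed
        frontier <- seed
        visited <- setNames(rep(FALSE, length(nms)), nms)
        visited[seed] <- TRUE
        while (length(frontier)) {
            nxt <- character()
            for (v in frontier) {
                nb <- sort(names(igraph::neighbors(graph, v)))
                nb <- nb[!visited[nb] & !assigned[nb] & weights[nb] >= thr]
                visited[nb] <- TRUE
                nxt <- c(nxt, nb)
            }
            members <- c(members, nxt)
            frontier <- nxt
        }
        sub <- igraph::induced_subgraph(graph, members)
        if (haircut) {
            core <- igraph::coreness(sub)
            keep <- names(core)[core >= 2]
            if (length(keep) < 2L) next
            sub <- igraph::induced_subgraph(graph, keep)
            members <- keep
        }
        n <- igraph::gorder(sub)
        if (n < 2L || igraph::gsize(sub) == 0L) next
        dens <- 2 * igraph::gsize(sub) / (n * (n - 1))
        assigned[members] <- TRUE
        out[[length(out) + 1L]] <- list(seed = seed, n = n, density = dens,
                                        score = dens * n,
                                        members = sort(members))
    }
    if (!length(out))
        return(data.frame(complex_id = integer(), seed = character(),
                          n = integer(), density = numeric(),
                          score = numeric(),
                          members = I(list()), stringsAsFactors = FALSE))
    ord <- order(-vapply(out, `[[`, 0, "score"),
                 vapply(out, `[[`, "", "seed"))
    out <- out[ord]
    data.frame(complex_id = seq_along(out),
               seed = vapply(out, `[[`, "", "seed"),
               n = vapply(out, function(x) as.integer(x$n), 0L),
               density = vapply(out, `[[`, 0, "density"),
               score = vapply(out, `[[`, 0, "score"),
               members = I(lapply(out, `[[`, "members")),
               stringsAsFactors = FALSE)
}

#' Apply the cluster-admission rules
#'
#' A complex is admitted when its MCODE score is strictly greater than
#' `mcodeMinScore`, it has at least `mcodeMinNodes` members ("more than
#' six nodes" under the defaults), and at least one member gene reaches
#' FDR < `fdrPrimary` in the differential-expression results. Genes absent
#' from the DE table are treated as non-qualifying.
#'
#' @param complexes data.frame from [mcodeFindComplexes()].
#' @param deTable data.frame with columns `gene_symbol` and `fdr` (best
#'   FDR per gene across contrasts).
#' @param config a [PipelineConfig-class].
#' @return `complexes` with added columns `score_ok`, `size_ok`, `fdr_ok`,
#'   `admitted` and `qualifying_gene` (best-FDR qualifying member, `NA` if
#'   none).
#' @export
admitComplexes <- function(complexes, deTable, config = pipelineConfig()) {
    stopifnot(all(c("gene_symbol", "fdr") %in% names(deTable)))
    bestFdr <- tapply(deTable$fdr, deTable$gene_symbol, min)
    res <- complexes
    res$score_ok <- res$score > config@mcodeMinScore
    res$size_ok <- res$n >= config@mcodeMinNodes
    qual <- lapply(complexes$members, function(m) {
        known <- m[m %in% names(bestFdr)]
        if (length(known) < length(m))
            .logStage("mcode", "%d member(s) absent from DE table",
                      length(m) - length(known))
        f <- bestFdr[known]
        f <- f[f < config@fdrPrimary]
        if (!length(f)) NA_character_ else names(f)[which.min(f)]
    })
    res$fdr_ok <- !is.na(unlist(qual))
    res$qualifying_gene <- unlist(qual)
    res$admitted <- res$score_ok & res$size_ok & res$fdr_ok
    res
}

#' Network stage: MCODE complexes with admission flags
#'
#' @param edges edge-list data.frame (see [readEdgeList()]) or an
#'   [igraph::igraph].
#' @param deTable gene-level table with `gene_symbol` and `fdr` (e.g. the
#'   row-bound deduplicated contrast tables from [deAnalysis()]).
#' @param config a [PipelineConfig-class].
#' @return annotated complex table (see [admitComplexes()]).
#' @export
mcodeComplexes <- function(edges, deTable, config = pipelineConfig()) {
    g <- if (inherits(edges, "igraph")) edges else geneGraph(edges)
    w <- mcodeVertexWeights(g)
    cx <- mcodeFindComplexes(g, w, vwp = config@mcodeVwp,
                             haircut = config@mcodeHaircut)
    .logStage("mcode", "%d vertices, %d edges -> %d complexes",
              igraph::gorder(g), igraph::gsize(g), nrow(cx))
    admitComplexes(cx, deTable, config)
}
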