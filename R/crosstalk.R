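#' Build the pathway crosstalk graph of a GLPAP set
#'
#' Connects two pathways when they "crosstalk": the weight of the pair is
#' the number of shared member genes plus the number of PPI edges with one
#' endpoint exclusive to the first pathway and the other exclusive to the
#' second. An edge is kept when the weight reaches `minCrosstalk`; pathways
#' left without any edge are dropped from the graph. Closeness centrality
#' (Wasserman-Faust, component-aware) and degree are computed for every
#' remaining node.
#'
#' @param glpaps a [GLPAPSet-class] or character vector of pathway ids.
#' @param db the [PathwayDB-class] supplying names, categories and members.
#' @param ppi an `igraph` PPI network (vertex names = gene ids).
#' @param minCrosstalk minimum weight for an edge (>= 1).
#' @return A [PathwayCrosstalkGraph-class].
#' @export
buildPathwayGraph <- function(glpaps, db, ppi, minCrosstalk = 1) {
    ids <- if (is(glpaps, "GLPAPSet")) pathwayIds(glpaps) else as.character(glpaps)
    if (!all(ids %in% pathwayIds(db)))
        stop("GLPAP ids not all present in the pathway database")
    if (minCrosstalk < 1) stop("minCrosstalk must be >= 1")
    if (length(ids) == 0L) {
        warning("empty GLPAP set: crosstalk graph is empty")
        return(emptyCrosstalkGraph())
    }
    sets <- geneSets(db)[ids]
    el <- igraph::as_edgelist(ppi, names = TRUE)
    # per-pathway membership masks over the two edge-endpoint columns
    m1 <- lapply(sets, function(g) el[, 1] %in% g)
    m2 <- lapply(sets, function(g) el[, 2] %in% g)
    np <- length(ids)
    edges <- list()
    for (i in seq_len(np - 1)) {
        for (j in seq(i + 1, np)) {
            shared <- length(intersect(sets[[i]], sets[[j]]))
            # bridging edges: one endpoint in P\Q, the other in Q\P
            bridge <- sum((m1[[i]] & !m1[[j]] & m2[[j]] & !m2[[i]]) |
                          (m1[[j]] & !m1[[i]] & m2[[i]] & !m2[[j]]))
            w <- shared + bridge
            if (w >= minCrosstalk)
                edges[[length(edges) + 1L]] <-
                    data.frame(pathway_a = ids[i], pathway_b = ids[j],
                               weight = w)
        }
    }
    if (length(edges) == 0L) {
        warning("no pathway pair reaches minCrosstalk: graph is empty")
        return(emptyCrosstalkGraph())
    }
    edges <- do.call(rbind, edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::E(g)$weight <- edges$weight
    keep <- igraph::V(g)$name
    clo <- closenessCentrality(g)
    nodes <- data.frame(
        pathway_id = keep,
        name = unname(pathwayNames(db)[keep]),
        category = unname(pathwayCategories(db)[keep]),
        closeness = unname(clo[keep]),
        degree = unname(igraph::degree(g)[keep]),
        row.names = NULL)
    new("PathwayCrosstalkGraph", graph = g, nodes = nodes, edges = edges)
}

emptyCrosstalkGraph <- function() {
    new("PathwayCrosstalkGraph",
        graph = igraph::make_empty_graph(0, directed = FALSE),
        nodes = data.frame(pathway_id = character(), name = character(),
                           category = character(), closeness = numeric(),
                           degree = integer()),
        edges = data.frame(pathway_a = character(), pathway_b = character(),
                           weight = numeric()))
}

#' Wasserman-Faust closeness centrality
#'
#' Component-aware closeness: for a node reaching `r` other nodes with total
#' shortest-path distance `S`, the centrality is `(r / (n - 1)) * (r / S)`
#' where `n` is the graph order. On a connected graph this reduces to the
#' classical `(n - 1) / S`; on a disconnected graph the first factor scales
#' values down so they stay comparable across components. Edge weights are
#' ignored (hop distances).
#'
#' @param graph an `igraph` object (or a [PathwayCrosstalkGraph-class]).
#' @return Named numeric vector of centralities, one per vertex; an
#'   isolated vertex gets 0.
#' @examples
#' p3 <- igraph::make_graph(~ a - b, b - c)
#' closenessCentrality(p3)  # center 1, leaves 2/3
#' @export
closenessCentrality <- function(graph) {
    if (is(graph, "PathwayCrosstalkGraph")) graph <- crosstalkGraph(graph)
    n <- igraph::vcount(graph)
    if (n == 0) return(numeric(0))
    if (n == 1) return(setNames(0, igraph::V(graph)$name))
    d <- igraph::distances(graph, weights = NA)
    vapply(seq_len(n), function(v) {
        dv <- d[v, -v]
        reach <- is.finite(dv)
        r <- sum(reach)
        if (r == 0) return(0)
        (r / (n - 1)) * (r / sum(dv[reach]))
    }, numeric(1)) |> setNames(rownames(d))
}

#' Select central pathways by the above-average rule
#'
#' A pathway is "central" when both its closeness centrality and its degree
#' are *strictly greater* than the corresponding cutoffs. By default the
#' cutoffs are the arithmetic means over all nodes of the graph (not only
#' the nodes of a restricted category); explicit cutoffs can be supplied,
#' e.g. to re-apply a published selection. With `restrictTo`, the selection
#' (not the cutoff computation) is limited to one category.
#'
#' @param x a [PathwayCrosstalkGraph-class], or a data.frame with at least
#'   `closeness` and `degree` columns (plus `pathway_id`/`category` if
#'   present).
#' @param restrictTo optional category label to restrict the selection to.
#' @param cutoffCloseness,cutoffDegree explicit cutoffs; `NULL` means the
#'   mean over all nodes of `x`.
#' @return List with `cutoff_closeness`, `cutoff_degree` and `selected` (the
#'   node rows exceeding both cutoffs, ordered by decreasing closeness).
#' @export
selectCentralPathways <- function(x, restrictTo = NULL,
                                  cutoffCloseness = NULL,
                                  cutoffDegree = NULL) {
    nodes <- if (is(x, "PathwayCrosstalkGraph")) nodeMetrics(x) else as.data.frame(x)
    if (nrow(nodes) == 0L) stop("graph has no nodes")
    if (is.null(cutoffCloseness)) cutoffCloseness <- mean(nodes$closeness)
    if (is.null(cutoffDegree)) cutoffDegree <- mean(nodes$degree)
    pool <- nodes
    if (!is.null(restrictTo)) {
        if (!"category" %in% names(pool))
            stop("restrictTo requires a 'category' column")
        pool <- pool[pool$category == restrictTo, ]
    }
    sel <- pool[pool$closeness > cutoffCloseness & pool$degree > cutoffDegree, ]
    sel <- sel[order(-sel$closeness), ]
    rownames(sel) <- NULL
    list(cutoff_closeness = cutoffCloseness,
         cutoff_degree = cutoffDegree,
         selected = sel)
}
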