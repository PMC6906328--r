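#' @import methods
#' @importFrom stats cor.test ks.test p.adjust phyper rank rlnorm rnorm runif
#'   setNames cor
#' @importFrom utils head read.delim write.table
NULL

#' Pathway database
#'
#' Container for a pathway collection: one display name, one category label
#' and one member-gene set per pathway. Mirrors a KEGG-style database where
#' every pathway belongs to exactly one top-level category (e.g. "Immune
#' system", "Signal transduction").
#'
#' @slot pathwayId character vector of unique pathway identifiers.
#' @slot pathwayName character vector of display names, parallel to
#'   `pathwayId`.
#' @slot category character vector of category labels, parallel to
#'   `pathwayId`. Categories are treated as a partition: each pathway has
#'   exactly one.
#' @slot genes list of character vectors; member gene ids per pathway.
#'
#' @seealso [PathwayDB()] for construction, [readPathwayGMT()] to read the
#'   extended-GMT representation.
#' @exportClass PathwayDB
setClass("PathwayDB",
    representation(
        pathwayId = "character",
        pathwayName = "character",
        category = "character",
        genes = "list"
    )
)

setValidity("PathwayDB", function(object) {
    n <- length(object@pathwayId)
    msg <- character()
    if (length(object@pathwayName) != n || length(object@category) != n ||
        length(object@genes) != n)
        msg <- c(msg, "pathwayId, pathwayName, category and genes must have equal length")
    if (anyDuplicated(object@pathwayId))
        msg <- c(msg, "pathway ids must be unique")
    if (n > 0 && any(!nzchar(object@category) | is.na(object@category)))
        msg <- c(msg, "every pathway needs a non-empty category")
    if (n > 0 && any(vapply(object@genes, length, 1L) == 0L))
        msg <- c(msg, "every pathway needs a non-empty gene set")
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayDB
#'
#' @param pathwayId character vector of unique pathway ids.
#' @param pathwayName character vector of display names (defaults to the
#'   ids).
#' @param category character vector of category labels.
#' @param genes list of character vectors of member gene ids.
#' @return A [PathwayDB-class] object.
#' @examples
#' db <- PathwayDB(c("p1", "p2"), category = c("immune", "metabolic"),
#'                 genes = list(c("g1", "g2", "g3"), c("g3", "g4", "g5")))
#' db
#' @export
PathwayDB <- function(pathwayId, pathwayName = pathwayId, category, genes) {
    new("PathwayDB",
        pathwayId = as.character(pathwayId),
        pathwayName = as.character(pathwayName),
        category = as.character(category),
        genes = lapply(genes, as.character))
}

#' Set of graft-loss-period activated pathways (GLPAPs)
#'
#' Result of intersecting the up-regulated significant pathways of the two
#' comparisons (within-subject graft-losing vs. baseline timepoint;
#' between-subject at the graft-losing timepoint).
#'
#' @slot ids character vector of selected pathway ids.
#' @slot provenance list recording the two comparison labels and the alpha
#'   threshold used.
#' @seealso [selectGLPAPs()]
#' @exportClass GLPAPSet
setClass("GLPAPSet",
    representation(ids = "character", provenance = "list"))

setValidity("GLPAPSet", function(object) {
    if (anyDuplicated(object@ids)) "pathway ids must be unique" else TRUE
})

#' Pathway crosstalk graph
#'
#' Undirected graph over GLPAPs. Two pathways are connected when their
#' crosstalk weight (shared genes plus PPI edges bridging their exclusive
#' members) reaches a threshold; pathways with no edge are dropped. Node
#' metrics (Wasserman-Faust closeness centrality and degree) are computed at
#' construction.
#'
#' @slot graph an `igraph` object whose vertices are pathway ids.
#' @slot nodes data.frame with columns `pathway_id`, `name`, `category`,
#'   `closeness`, `degree`.
#' @slot edges data.frame with columns `pathway_a`, `pathway_b`, `weight`.
#' @seealso [buildPathwayGraph()], [selectCentralPathways()]
#' @exportClass PathwayCrosstalkGraph
setClass("PathwayCrosstalkGraph",
    representation(graph = "ANY", nodes = "data.frame", edges = "data.frame"))

setValidity("PathwayCrosstalkGraph", function(object) {
    msg <- character()
    need <- c("pathway_id", "name", "category", "closeness", "degree")
    if (!all(need %in% names(object@nodes)))
        msg <- c(msg, "nodes must have pathway_id, name, category, closeness, degree")
    if (!all(c("pathway_a", "pathway_b", "weight") %in% names(object@edges)))
        msg <- c(msg, "edges must have pathway_a, pathway_b, weight")
    if (length(msg)) msg else TRUE
})

#' Hypothesis evaluation results
#'
#' One row per etiological hypothesis: rank-correlation coefficient between
#' the network-propagation ranking and the differential-expression ranking,
#' its parametric p-value, and the empirical p-value from random seed
#' simulations. The per-hypothesis random coefficients are kept so the
#' empirical null can be inspected.
#'
#' @slot table data.frame sorted by descending coefficient.
#' @slot randomCoefficients named list, one numeric vector of simulated
#'   coefficients per hypothesis.
#' @slot parameters list of the propagation / simulation parameters used.
#' @seealso [evaluateHypotheses()]
#' @exportClass HypothesisEvaluation
setClass("HypothesisEvaluation",
    representation(table = "data.frame", randomCoefficients = "list",
                   parameters = "list"))
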