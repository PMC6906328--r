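#' @rdname PathwayDB-class
#' @param x,object a `PathwayDB` (or other class as documented).
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname PathwayDB-class
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname PathwayDB-class
#' @export
setGeneric("pathwayCategories", function(x) standardGeneric("pathwayCategories"))

#' @rdname PathwayDB-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname PathwayCrosstalkGraph-class
#' @param x,object a `PathwayCrosstalkGraph`.
#' @export
setGeneric("nodeMetrics", function(x) standardGeneric("nodeMetrics"))

#' @rdname PathwayCrosstalkGraph-class
#' @export
setGeneric("crosstalkEdges", function(x) standardGeneric("crosstalkEdges"))

#' @rdname PathwayCrosstalkGraph-class
#' @export
setGeneric("crosstalkGraph", function(x) standardGeneric("crosstalkGraph"))

#' @rdname HypothesisEvaluation-class
#' @param x,object a `HypothesisEvaluation`.
#' @export
setGeneric("hypothesisTable", function(x) standardGeneric("hypothesisTable"))

#' @rdname HypothesisEvaluation-class
#' @export
setGeneric("randomCoefficients", function(x) standardGeneric("randomCoefficients"))

## ---- PathwayDB methods ----

#' @rdname PathwayDB-class
#' @export
setMethod("pathwayIds", "PathwayDB", function(x) x@pathwayId)

#' @rdname PathwayDB-class
#' @export
setMethod("pathwayNames", "PathwayDB",
    function(x) setNames(x@pathwayName, x@pathwayId))

#' @rdname PathwayDB-class
#' @export
setMethod("pathwayCategories", "PathwayDB",
    function(x) setNames(x@category, x@pathwayId))

#' @rdname PathwayDB-class
#' @export
setMethod("geneSets", "PathwayDB",
    function(x) setNames(x@genes, x@pathwayId))

#' @rdname PathwayDB-class
#' @export
setMethod("length", "PathwayDB", function(x) length(x@pathwayId))

#' @rdname PathwayDB-class
#' @param i index (pathway ids, logical or integer) for subsetting.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PathwayDB", function(x, i, j, ..., drop = FALSE) {
    idx <- if (is.character(i)) match(i, x@pathwayId) else seq_along(x@pathwayId)[i]
    if (anyNA(idx)) stop("unknown pathway id in subset")
    PathwayDB(x@pathwayId[idx], x@pathwayName[idx], x@category[idx],
              x@genes[idx])
})

setMethod("show", "PathwayDB", function(object) {
    cat("PathwayDB with", length(object), "pathways in",
        length(unique(object@category)), "categories\n")
    if (length(object) > 0) {
        sizes <- vapply(object@genes, length, 1L)
        cat("  gene-set sizes:", min(sizes), "-", max(sizes),
            "(median", stats::median(sizes), ")\n")
        cat("  categories:", paste(head(sort(unique(object@category)), 5),
                                   collapse = ", "),
            if (length(unique(object@category)) > 5) "..." else "", "\n")
    }
})

## ---- GLPAPSet methods ----

#' @rdname GLPAPSet-class
#' @param x,object a `GLPAPSet`.
#' @export
setMethod("pathwayIds", "GLPAPSet", function(x) x@ids)

#' @rdname GLPAPSet-class
#' @export
setMethod("length", "GLPAPSet", function(x) length(x@ids))

setMethod("show", "GLPAPSet", function(object) {
    cat("GLPAPSet with", length(object@ids), "pathways\n")
    prov <- object@provenance
    if (length(prov))
        cat("  comparisons:", paste(unlist(prov$comparisons), collapse = " & "),
            "at alpha <", prov$alpha, "\n")
    if (length(object@ids))
        cat("  ", paste(head(object@ids, 8), collapse = ", "),
            if (length(object@ids) > 8) "..." else "", "\n")
})

## ---- PathwayCrosstalkGraph methods ----

#' @rdname PathwayCrosstalkGraph-class
#' @export
setMethod("nodeMetrics", "PathwayCrosstalkGraph", function(x) x@nodes)

#' @rdname PathwayCrosstalkGraph-class
#' @export
setMethod("crosstalkEdges", "PathwayCrosstalkGraph", function(x) x@edges)

#' @rdname PathwayCrosstalkGraph-class
#' @export
setMethod("crosstalkGraph", "PathwayCrosstalkGraph", function(x) x@graph)

setMethod("show", "PathwayCrosstalkGraph", function(object) {
    cat("PathwayCrosstalkGraph:", nrow(object@nodes), "pathways,",
        nrow(object@edges), "edges\n")
    if (nrow(object@nodes)) {
        cat("  mean closeness:", signif(mean(object@nodes$closeness), 4),
            " mean degree:", signif(mean(object@nodes$degree), 4), "\n")
    }
})

## ---- HypothesisEvaluation methods ----

#' @rdname HypothesisEvaluation-class
#' @export
setMethod("hypothesisTable", "HypothesisEvaluation", function(x) x@table)

#' @rdname HypothesisEvaluation-class
#' @export
setMethod("randomCoefficients", "HypothesisEvaluation",
    function(x) x@randomCoefficients)

setMethod("show", "HypothesisEvaluation", function(object) {
    cat("HypothesisEvaluation over", nrow(object@table), "hypotheses",
        sprintf("(%d random simulations)\n",
                object@parameters$nSim %||% NA_integer_))
    print(object@table, row.names = FALSE, digits = 4)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
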