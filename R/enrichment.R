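#' Select graft-loss-period activated pathways (GLPAPs)
#'
#' Intersects two activity-comparison results: a pathway is a GLPAP when it
#' is up-regulated with p-value strictly below `alpha` in *both* the
#' within-subject comparison (graft-losing vs. baseline timepoint of the
#' failing subject) and the between-subject comparison (failing vs. stable
#' subject at the graft-losing timepoint). Untestable pathways (no gene in a
#' profile) are never selected.
#'
#' @param resultsA,resultsB data.frames from [scorePathwayActivity()], over
#'   the same pathway database.
#' @param alpha significance threshold in (0, 1); the comparison is strict
#'   (`p < alpha`), so a p-value exactly at `alpha` is excluded.
#' @return A [GLPAPSet-class].
#' @export
selectGLPAPs <- function(resultsA, resultsB, alpha = 0.05) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (!setequal(resultsA$pathway_id, resultsB$pathway_id) ||
        nrow(resultsA) != nrow(resultsB))
        stop("the two comparisons cover different pathway sets")
    resultsB <- resultsB[match(resultsA$pathway_id, resultsB$pathway_id), ]
    sig <- function(r) r$testable & !is.na(r$p_value) &
        r$direction == "up" & r$p_value < alpha
    ids <- resultsA$pathway_id[sig(resultsA) & sig(resultsB)]
    new("GLPAPSet", ids = as.character(ids),
        provenance = list(
            comparisons = list(unique(resultsA$comparison),
                               unique(resultsB$comparison)),
            alpha = alpha))
}

#' One-sided Fisher's exact test for enrichment
#'
#' Exact hypergeometric tail probability `P(X >= a)` for a 2x2 contingency
#' table with fixed margins — the one-sided ("greater") Fisher test. Used to
#' ask whether selected pathways are over-represented in a category. All
#' arguments are vectorized.
#'
#' @param a selected pathways in the category.
#' @param b selected pathways not in the category.
#' @param c_ unselected pathways in the category.
#' @param d unselected pathways not in the category.
#' @return p-value(s) in (0, 1].
#' @examples
#' fisherOneSided(1, 0, 0, 1)  # two equiprobable tables -> 0.5
#' @export
fisherOneSided <- function(a, b, c_, d) {
    if (any(c(a, b, c_, d) < 0)) stop("contingency counts must be >= 0")
    # X ~ Hypergeom(white = a + c_ in category, black = b + d, drawn = a + b)
    stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Category enrichment of a GLPAP set
#'
#' For every category of the database, builds the 2x2 contingency table
#' (GLPAP x in-category) and computes the one-sided Fisher p-value. Raw
#' p-values are reported without multiple-testing correction, sorted
#' ascending (ties broken by category name), mirroring how category
#' enrichment tables are usually presented.
#'
#' @param glpaps a [GLPAPSet-class] (or character vector of pathway ids).
#' @param db the [PathwayDB-class] the selection was made from.
#' @return data.frame with columns `category`, `a`, `b`, `c`, `d`,
#'   `p_value`, sorted ascending by `p_value`.
#' @export
enrichCategories <- function(glpaps, db) {
    ids <- if (is(glpaps, "GLPAPSet")) pathwayIds(glpaps) else as.character(glpaps)
    if (!all(ids %in% pathwayIds(db)))
        stop("GLPAP ids not all present in the pathway database")
    if (length(ids) == 0L)
        warning("empty GLPAP set: all enrichment p-values are 1")
    cats <- pathwayCategories(db)
    isG <- pathwayIds(db) %in% ids
    out <- do.call(rbind, lapply(sort(unique(unname(cats))), function(ct) {
        inC <- unname(cats) == ct
        a <- sum(isG & inC); b <- sum(isG & !inC)
        c_ <- sum(!isG & inC); d <- sum(!isG & !inC)
        data.frame(category = ct, a = a, b = b, c = c_, d = d,
                   p_value = fisherOneSided(a, b, c_, d))
    }))
    out <- out[order(out$p_value, out$category), ]
    rownames(out) <- NULL
    out
}
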