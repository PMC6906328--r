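#' Per-gene log2 fold change between two samples
#'
#' Computes `log2(a/b)` per gene between two (subject, timepoint) samples,
#' after discarding every gene whose abundance is below `minExpression` in
#' *either* sample. The filter (default 1) prevents extreme ratios driven by
#' near-zero denominators or numerators; it is the standard guard when fold
#' changes are taken between single samples rather than replicated groups.
#'
#' @param se expression `SummarizedExperiment` (see [ExpressionSE()]).
#' @param sampleA,sampleB length-2 character vectors `c(subject, timepoint)`;
#'   `sampleA` is the numerator (case / graft-losing side).
#' @param minExpression non-negative filter threshold; genes with abundance
#'   `< minExpression` in either sample are dropped before the ratio is
#'   taken.
#' @return Named numeric vector of log2 fold changes for the surviving
#'   genes.
#' @examples
#' m <- rbind(g1 = c(4, 2), g2 = c(0.5, 10), g3 = c(3, 3))
#' se <- ExpressionSE(m, c("case", "ctrl"), c("t3", "t3"))
#' geneLog2FC(se, c("case", "t3"), c("ctrl", "t3"))  # g2 filtered out
#' @export
geneLog2FC <- function(se, sampleA, sampleB, minExpression = 1) {
    if (minExpression < 0) stop("minExpression must be >= 0")
    a <- sampleValues(se, sampleA[[1]], sampleA[[2]])
    b <- sampleValues(se, sampleB[[1]], sampleB[[2]])
    keep <- a >= minExpression & b >= minExpression
    a <- a[keep]; b <- b[keep]
    if (any(b == 0 | a == 0))
        stop("zero abundance survived the filter; raise minExpression above 0")
    log2(a / b)
}

#' Competitive permutation test for pathway up-regulation
#'
#' Stand-in for a pathway activation score: the statistic is the mean log2
#' fold change over the pathway's genes present in the profile, and the
#' one-sided (up-regulation) p-value is obtained by comparing it against
#' means of random same-size gene sets drawn from the profiled universe.
#' The Monte-Carlo p uses the add-one correction
#' `(1 + #{perm >= obs}) / (nPermutations + 1)` so it is never zero and is
#' valid at any number of permutations; with `exact = TRUE` every subset of
#' the universe is enumerated instead and the p-value is the exact tail
#' fraction `#{subset mean >= obs} / C(n, k)`.
#'
#' @param log2fc named numeric vector from [geneLog2FC()]; the gene
#'   universe of the test.
#' @param pathwayGenes character vector of member gene ids.
#' @param nPermutations number of random gene sets (>= 100).
#' @param rngSeed optional integer seed for reproducible permutations.
#' @param exact enumerate all `C(n, k)` subsets instead of sampling
#'   (feasible only for small universes).
#' @return List with `statistic` (mean log2FC), `direction` (`"up"` iff
#'   statistic > 0), `p_value` (one-sided, up), `n_used` (pathway genes
#'   present) and `testable`. A pathway with no gene in the profile returns
#'   `testable = FALSE` and NA statistic/p (it is excluded downstream, not
#'   an error).
#' @export
pathwayActivationTest <- function(log2fc, pathwayGenes, nPermutations = 999,
                                  rngSeed = NULL, exact = FALSE) {
    present <- intersect(pathwayGenes, names(log2fc))
    k <- length(present)
    if (k == 0L)
        return(list(statistic = NA_real_, direction = NA_character_,
                    p_value = NA_real_, n_used = 0L, testable = FALSE))
    if (!exact && nPermutations < 100) stop("nPermutations must be >= 100")
    x <- unname(log2fc)
    n <- length(x)
    stat <- mean(log2fc[present])
    if (exact) {
        if (choose(n, k) > 5e5)
            stop("exact enumeration infeasible: C(n, k) too large")
        sums <- utils::combn(x, k, sum)
        # tolerance so the observed subset always counts itself despite
        # float summation order
        p <- sum(sums / k >= stat - 1e-12) / length(sums)
    } else {
        if (!is.null(rngSeed)) set.seed(rngSeed)
        perm <- vapply(seq_len(nPermutations),
                       function(i) sum(x[sample.int(n, k)]) / k, numeric(1))
        p <- (1 + sum(perm >= stat - 1e-12)) / (nPermutations + 1)
    }
    list(statistic = stat,
         direction = if (stat > 0) "up" else "down",
         p_value = p, n_used = k, testable = TRUE)
}

#' Score up-regulation of every pathway in a database
#'
#' Applies [pathwayActivationTest()] to each pathway of `db` against one
#' log2 fold-change profile (one comparison of the study design).
#'
#' @param se expression `SummarizedExperiment`.
#' @param db a [PathwayDB-class].
#' @param sampleA,sampleB the comparison, as in [geneLog2FC()].
#' @param label comparison label stored in the result (e.g. `"case_t3_vs_t2"`).
#' @param minExpression abundance filter, see [geneLog2FC()].
#' @param nPermutations,rngSeed permutation settings.
#' @return data.frame with one row per pathway: `pathway_id`, `name`,
#'   `category`, `comparison`, `n_used`, `statistic`, `direction`,
#'   `p_value`, `testable`.
#' @export
scorePathwayActivity <- function(se, db, sampleA, sampleB,
                                 label = paste(sampleA, collapse = "_"),
                                 minExpression = 1, nPermutations = 999,
                                 rngSeed = NULL) {
    lfc <- geneLog2FC(se, sampleA, sampleB, minExpression)
    if (!is.null(rngSeed)) set.seed(rngSeed)
    res <- lapply(geneSets(db), function(gs)
        pathwayActivationTest(lfc, gs, nPermutations))
    data.frame(
        pathway_id = pathwayIds(db),
        name = unname(pathwayNames(db)),
        category = unname(pathwayCategories(db)),
        comparison = label,
        n_used = vapply(res, function(r) r$n_used, 1L),
        statistic = vapply(res, function(r) r$statistic, 1),
        direction = vapply(res, function(r) as.character(r$direction), ""),
        p_value = vapply(res, function(r) r$p_value, 1),
        testable = vapply(res, function(r) r$testable, TRUE),
        row.names = NULL)
}
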