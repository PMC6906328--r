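#' Differential-expression profile for hypothesis evaluation
#'
#' Builds the per-gene log2 fold-change profile between a case and a
#' control sample (after the abundance filter of [geneLog2FC()]) and ranks
#' the genes, rank 1 being the most up-regulated (`rankBy = "signed"`,
#' default) or the most changed in either direction (`rankBy =
#' "absolute"`). Ties receive mid-ranks.
#'
#' @param se expression `SummarizedExperiment`.
#' @param case,control length-2 vectors `c(subject, timepoint)`.
#' @param minExpression abundance filter (genes below it in either sample
#'   are excluded before ranking).
#' @param rankBy ranking key: signed log2FC (descending) or its absolute
#'   value (descending).
#' @return data.frame with columns `gene`, `log2fc`, `rank`.
#' @export
buildDEGProfile <- function(se, case, control, minExpression = 1,
                            rankBy = c("signed", "absolute")) {
    rankBy <- match.arg(rankBy)
    lfc <- geneLog2FC(se, case, control, minExpression)
    if (length(lfc) == 0L)
        stop("no gene survives the expression filter")
    key <- if (rankBy == "signed") lfc else abs(lfc)
    data.frame(gene = names(lfc), log2fc = unname(lfc),
               rank = rank(-key, ties.method = "average"),
               row.names = NULL)
}

#' Random-walk-with-restart network propagation
#'
#' Diffuses seed-gene influence over the PPI network by iterating
#' `s <- (1 - r) W s + r s0` to its fixed point, where `s0` is uniform over
#' the seed genes, `r` the restart probability, and `W` the normalized
#' adjacency matrix: degree-symmetric `D^-1/2 A D^-1/2` (default) or
#' column-stochastic `A D^-1`. The fixed point equals the direct solution
#' `r (I - (1 - r) W)^-1 s0`; iteration converges geometrically since the
#' spectral radius of `(1 - r) W` is below 1.
#'
#' @param ppi `igraph` PPI network, vertex names = gene ids.
#' @param seeds character vector of seed gene ids; seeds absent from the
#'   network are dropped with a warning (error if none remains).
#' @param restartProb restart probability in (0, 1); default 0.5.
#' @param tol L1 convergence tolerance on successive score vectors.
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param normalization adjacency normalization, see Details.
#' @return List with `scores` (named, >= 0), `rank` (mid-ranks, 1 = most
#'   influenced), `seeds_used`, and `parameters`.
#' @export
propagateSeeds <- function(ppi, seeds, restartProb = 0.5, tol = 1e-10,
                           maxIter = 10000,
                           normalization = c("symmetric", "column")) {
    normalization <- match.arg(normalization)
    if (restartProb <= 0 || restartProb >= 1)
        stop("restartProb must be in (0, 1)")
    genes <- igraph::V(ppi)$name
    seeds <- unique(as.character(seeds))
    missing <- setdiff(seeds, genes)
    if (length(missing)) {
        warning(sprintf("%d seed gene(s) not in the network, dropped: %s",
                        length(missing),
                        paste(head(missing, 5), collapse = ", ")))
        seeds <- setdiff(seeds, missing)
    }
    if (length(seeds) == 0L) stop("no seed gene maps to the network")
    W <- normalizedAdjacency(ppi, normalization)
    s0 <- setNames(numeric(length(genes)), genes)
    s0[seeds] <- 1 / length(seeds)
    s <- s0
    r <- restartProb
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        snew <- as.numeric((1 - r) * (W %*% s)) + r * s0
        delta <- sum(abs(snew - s))
        s <- snew
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        stop(sprintf("propagation did not converge in %d iterations (L1 residual %.3g)",
                     maxIter, delta))
    names(s) <- genes
    list(scores = s,
         rank = rank(-s, ties.method = "average"),
         seeds_used = seeds,
         parameters = list(restart_prob = r, tol = tol, max_iter = maxIter,
                           normalization = normalization, iterations = it))
}

normalizedAdjacency <- function(ppi, normalization) {
    A <- igraph::as_adjacency_matrix(ppi, sparse = TRUE)
    deg <- Matrix::colSums(A)
    inv <- ifelse(deg > 0, 1 / deg, 0)  # isolated nodes keep zero columns
    if (normalization == "symmetric") {
        Dhalf <- Matrix::Diagonal(x = sqrt(inv))
        Dhalf %*% A %*% Dhalf
    } else {
        A %*% Matrix::Diagonal(x = inv)
    }
}

#' Rank correlation between propagation and differential expression
#'
#' Pearson correlation of the two rank vectors restricted to the genes
#' present in both the propagation result and the DEG profile (equivalently
#' a Spearman correlation of the underlying scores), with the parametric
#' p-value from the t-distribution. Both vectors are re-ranked within the
#' intersection so ties keep their mid-rank structure.
#'
#' @param prop result of [propagateSeeds()].
#' @param deg data.frame from [buildDEGProfile()].
#' @return List with `coefficient`, `parametric_p`, `n_genes`.
#' @export
rankCorrelation <- function(prop, deg) {
    common <- intersect(names(prop$scores), deg$gene)
    if (length(common) < 3L)
        stop("need at least 3 genes shared by propagation result and DEG profile")
    x <- rank(prop$rank[common], ties.method = "average")
    y <- rank(deg$rank[match(common, deg$gene)], ties.method = "average")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        stop("constant rank vector: correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(coefficient = unname(ct$estimate), parametric_p = ct$p.value,
         n_genes = length(common))
}

#' Rank correlation over the k most-influenced genes
#'
#' Restricts to the `k` genes with the best propagation ranks among those
#' shared with the DEG profile (ties at the boundary broken by gene id),
#' re-ranks both vectors, and applies [rankCorrelation()].
#'
#' @inheritParams rankCorrelation
#' @param k number of top genes (3 <= k <= number of shared genes).
#' @return As [rankCorrelation()].
#' @export
topKCorrelation <- function(prop, deg, k) {
    common <- intersect(names(prop$scores), deg$gene)
    if (k > length(common))
        stop("k exceeds the number of genes shared with the DEG profile")
    ord <- common[order(-prop$scores[common], common)]
    top <- ord[seq_len(k)]
    sub <- list(scores = prop$scores[top],
                rank = rank(-prop$scores[top], ties.method = "average"))
    rankCorrelation(sub, deg[deg$gene %in% top, , drop = FALSE])
}

#' Empirical p-value from a simulated coefficient null
#'
#' The literal empirical p: the fraction of simulated coefficients strictly
#' exceeding the reference, `p = (1/N) * #{c_j > c_ref}` — no pseudocount,
#' so 0 and 1 are attainable. A positively biased (add-one) variant is
#' available for guaranteed-valid p-values.
#'
#' @param coefficients numeric vector of simulated coefficients.
#' @param reference observed (reference) coefficient.
#' @param correction `"none"` (literal formula, default) or `"add_one"`
#'   (`(1 + #exceed) / (N + 1)`).
#' @return Empirical p-value on the lattice `{0, 1/N, ..., 1}` (`"none"`).
#' @examples
#' empiricalP(c(rep(0.01, 990), rep(0.9, 10)), 0.5)  # 0.010
#' @export
empiricalP <- function(coefficients, reference,
                       correction = c("none", "add_one")) {
    correction <- match.arg(correction)
    n <- length(coefficients)
    exceed <- sum(coefficients > reference)
    if (correction == "none") exceed / n else (1 + exceed) / (n + 1)
}

#' Empirical p-value by random seed simulation
#'
#' Draws `nSim` random seed sets of the given size, recomputes the
#' (optionally top-k) rank-correlation coefficient for each, and returns
#' the fraction strictly exceeding the reference coefficient. Samplers:
#' `"uniform"` draws seeds uniformly from the network's genes;
#' `"degree_matched"` draws one gene per reference seed from the same
#' log2-degree bin (nearest non-empty bin with a warning when a bin is
#' unpopulated).
#'
#' @param ppi `igraph` PPI network.
#' @param deg DEG profile data.frame.
#' @param seedSize number of genes per random seed set.
#' @param referenceCoeff observed coefficient being tested.
#' @param nSim number of random simulations (>= 1).
#' @param sampler `"uniform"` or `"degree_matched"`.
#' @param referenceSeeds reference seed set; required for
#'   `"degree_matched"`.
#' @param rngSeed optional integer seed.
#' @param k optional top-k restriction matching the reference coefficient.
#' @param restartProb,tol,maxIter,normalization propagation settings.
#' @param correction passed to [empiricalP()].
#' @return List with `empirical_p`, `n_sim`, `random_coefficients`.
#' @export
empiricalPvalue <- function(ppi, deg, seedSize, referenceCoeff, nSim = 1000,
                            sampler = c("uniform", "degree_matched"),
                            referenceSeeds = NULL, rngSeed = NULL, k = NULL,
                            restartProb = 0.5, tol = 1e-8, maxIter = 10000,
                            normalization = "symmetric",
                            correction = "none") {
    sampler <- match.arg(sampler)
    if (nSim < 1 || seedSize < 1) stop("nSim and seedSize must be >= 1")
    if (!is.null(rngSeed)) set.seed(rngSeed)
    genes <- igraph::V(ppi)$name
    drawSeeds <- if (sampler == "uniform") {
        function() sample(genes, seedSize)
    } else {
        if (is.null(referenceSeeds))
            stop("degree_matched sampling needs the reference seed set")
        makeDegreeMatchedSampler(ppi, referenceSeeds)
    }
    cj <- vapply(seq_len(nSim), function(j) {
        pr <- propagateSeeds(ppi, drawSeeds(), restartProb, tol, maxIter,
                             normalization)
        if (is.null(k)) rankCorrelation(pr, deg)$coefficient
        else topKCorrelation(pr, deg, k)$coefficient
    }, numeric(1))
    list(empirical_p = empiricalP(cj, referenceCoeff, correction),
         n_sim = nSim, random_coefficients = cj)
}

## one random gene per reference seed, matched on floor(log2(degree + 1))
makeDegreeMatchedSampler <- function(ppi, referenceSeeds) {
    genes <- igraph::V(ppi)$name
    degs <- igraph::degree(ppi)
    bin <- floor(log2(degs + 1))
    refBins <- bin[match(intersect(referenceSeeds, genes), genes)]
    pool <- split(genes, bin)
    levels <- as.numeric(names(pool))
    function() {
        picks <- vapply(refBins, function(bv) {
            key <- as.character(bv)
            if (!key %in% names(pool) || length(pool[[key]]) == 0L) {
                warning("empty degree bin; falling back to nearest bin")
                key <- as.character(levels[which.min(abs(levels - bv))])
            }
            sample(pool[[key]], 1)
        }, character(1))
        unique(picks)
    }
}

#' Evaluate etiological hypotheses by network propagation
#'
#' For each hypothesis seed set: propagate over the PPI, correlate the
#' propagation ranking with the DEG-profile ranking (all shared genes, and
#' optionally the top-k most-influenced genes), and compute the empirical
#' p-value of the full-profile coefficient against `nSim` random seed sets
#' of the same size. The hypothesis whose seeds best reproduce the observed
#' expression change ranks first.
#'
#' @param ppi `igraph` PPI network.
#' @param deg DEG profile from [buildDEGProfile()].
#' @param seeds named list of character vectors, one seed set per
#'   hypothesis; names must be unique.
#' @param nSim random simulations per hypothesis for the empirical p.
#' @param topK optional k for an additional top-k coefficient (e.g. 100);
#'   `NULL` to skip.
#' @param sampler,rngSeed,restartProb,tol,maxIter,normalization,correction
#'   see [empiricalPvalue()] and [propagateSeeds()].
#' @return A [HypothesisEvaluation-class]; its table is sorted by
#'   descending coefficient.
#' @export
evaluateHypotheses <- function(ppi, deg, seeds, nSim = 1000, topK = NULL,
                               sampler = "uniform", rngSeed = NULL,
                               restartProb = 0.5, tol = 1e-8,
                               maxIter = 10000,
                               normalization = "symmetric",
                               correction = "none") {
    if (length(seeds) < 1L) stop("need at least one hypothesis")
    if (is.null(names(seeds)) || anyDuplicated(names(seeds)))
        stop("hypotheses need unique names")
    if (!is.null(rngSeed)) set.seed(rngSeed)
    subSeeds <- sample.int(.Machine$integer.max, length(seeds))
    rows <- list(); rand <- list()
    for (i in seq_along(seeds)) {
        nm <- names(seeds)[i]
        pr <- propagateSeeds(ppi, seeds[[i]], restartProb, tol, maxIter,
                             normalization)
        rc <- rankCorrelation(pr, deg)
        tk <- if (!is.null(topK)) topKCorrelation(pr, deg, topK) else NULL
        ep <- empiricalPvalue(ppi, deg, seedSize = length(pr$seeds_used),
                              referenceCoeff = rc$coefficient, nSim = nSim,
                              sampler = sampler,
                              referenceSeeds = pr$seeds_used,
                              rngSeed = subSeeds[i], k = NULL,
                              restartProb = restartProb, tol = tol,
                              maxIter = maxIter,
                              normalization = normalization,
                              correction = correction)
        rows[[nm]] <- data.frame(
            hypothesis = nm,
            n_seeds = length(pr$seeds_used),
            coefficient = rc$coefficient,
            parametric_p = rc$parametric_p,
            empirical_p = ep$empirical_p,
            topk_coefficient = if (is.null(tk)) NA_real_ else tk$coefficient,
            topk_parametric_p = if (is.null(tk)) NA_real_ else tk$parametric_p)
        rand[[nm]] <- ep$random_coefficients
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$coefficient), ]
    rownames(tab) <- NULL
    new("HypothesisEvaluation", table = tab, randomCoefficients = rand,
        parameters = list(nSim = nSim, topK = topK, sampler = sampler,
                          restartProb = restartProb, tol = tol,
                          maxIter = maxIter, normalization = normalization,
                          correction = correction))
}
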