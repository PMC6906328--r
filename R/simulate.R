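#' Configuration for the synthetic graft-loss dataset
#'
#' Validated parameter list for [simulateGraftLossDataset()]. The defaults
#' emulate the study design the pipeline targets: two subjects (one losing
#' the graft, one stable) sampled at four timepoints t1..t4, a KEGG-sized
#' pathway collection (287 pathways in 17 categories over 6,780 genes), a
#' scale-free PPI whose density matches a curated interactome (~17 edges
#' attached per node, i.e. ~118k edges on ~6.8k nodes), and five
#' etiological hypotheses with seed sets of sizes 10/9/8/10/9 whose fourth
#' entry (chronic graft rejection) is causal.
#'
#' @param nGenes number of genes.
#' @param nPathways,nCategories pathway collection shape; categories
#'   partition the pathways.
#' @param pathwaySizeRange c(min, max) member genes per pathway (min >= 3);
#'   genes may belong to several pathways.
#' @param subjects character vector of subject ids (first = case).
#' @param timepoints ordered timepoint labels.
#' @param baselineLogmean,baselineLogsd log-normal baseline: each gene draws
#'   one mean log-expression, shared across samples.
#' @param noiseLogsd per-sample log-scale noise sd.
#' @param activatedPathways pathway ids to plant as activated, or an
#'   integer count (the pathways are then drawn from a single category so
#'   category enrichment is recoverable).
#' @param activationFold multiplicative fold (> 1, or exactly 1 for a null
#'   dataset) applied to the planted pathways' member genes at one
#'   (subject, timepoint) cell.
#' @param activationSubject,activationTimepoint the activated cell;
#'   defaults: the case subject at t3 (the graft-losing period).
#' @param ppiEdgesPerNode preferential-attachment edges per added node.
#' @param nHypotheses,seedSetSizes,causalHypothesisIndex hypothesis layout;
#'   the causal hypothesis' seeds are planted adjacent to the
#'   differentially expressed genes.
#' @param hypothesisNames optional character vector of unique names.
#' @param rngSeed integer seed making the whole dataset reproducible.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 6780, nPathways = 287,
                             nCategories = 17,
                             pathwaySizeRange = c(10, 80),
                             subjects = c("case", "control"),
                             timepoints = c("t1", "t2", "t3", "t4"),
                             baselineLogmean = 3, baselineLogsd = 1,
                             noiseLogsd = 0.25,
                             activatedPathways = 5,
                             activationFold = 4,
                             activationSubject = subjects[1],
                             activationTimepoint = "t3",
                             ppiEdgesPerNode = 17,
                             nHypotheses = 5,
                             seedSetSizes = c(10, 9, 8, 10, 9),
                             causalHypothesisIndex = 4,
                             hypothesisNames = NULL,
                             rngSeed = 1) {
    cfg <- list(nGenes = as.integer(nGenes), nPathways = as.integer(nPathways),
                nCategories = as.integer(nCategories),
                pathwaySizeRange = as.integer(pathwaySizeRange),
                subjects = subjects, timepoints = timepoints,
                baselineLogmean = baselineLogmean,
                baselineLogsd = baselineLogsd, noiseLogsd = noiseLogsd,
                activatedPathways = activatedPathways,
                activationFold = activationFold,
                activationSubject = activationSubject,
                activationTimepoint = activationTimepoint,
                ppiEdgesPerNode = as.integer(ppiEdgesPerNode),
                nHypotheses = as.integer(nHypotheses),
                seedSetSizes = as.integer(seedSetSizes),
                causalHypothesisIndex = as.integer(causalHypothesisIndex),
                hypothesisNames = hypothesisNames,
                rngSeed = as.integer(rngSeed))
    if (is.null(cfg$hypothesisNames))
        cfg$hypothesisNames <- paste0("hypothesis_",
                                      seq_len(cfg$nHypotheses))
    validateSimulationConfig(cfg)
    class(cfg) <- "SimulationConfig"
    cfg
}

validateSimulationConfig <- function(cfg) {
    if (cfg$pathwaySizeRange[1] < 3)
        stop("minimum pathway size must be >= 3")
    if (cfg$pathwaySizeRange[2] < cfg$pathwaySizeRange[1])
        stop("pathwaySizeRange must be increasing")
    if (cfg$pathwaySizeRange[2] > cfg$nGenes)
        stop("pathway sizes infeasible for nGenes")
    if (cfg$activationFold < 1)
        stop("activationFold must be >= 1 (1 = null dataset)")
    if (anyDuplicated(cfg$timepoints)) stop("timepoints must be unique")
    if (anyDuplicated(cfg$subjects)) stop("subjects must be unique")
    if (length(cfg$seedSetSizes) != cfg$nHypotheses)
        stop("seedSetSizes must have one entry per hypothesis")
    if (any(cfg$seedSetSizes < 1)) stop("seed set sizes must be >= 1")
    if (anyDuplicated(cfg$hypothesisNames))
        stop("duplicate hypothesis names")
    if (length(cfg$hypothesisNames) != cfg$nHypotheses)
        stop("hypothesisNames must have one entry per hypothesis")
    if (cfg$causalHypothesisIndex < 1 ||
        cfg$causalHypothesisIndex > cfg$nHypotheses)
        stop("causalHypothesisIndex out of range")
    if (!cfg$activationSubject %in% cfg$subjects ||
        !cfg$activationTimepoint %in% cfg$timepoints)
        stop("activation cell outside the sampling design")
    invisible(cfg)
}

#' Simulate a complete graft-loss dataset with ground truth
#'
#' Generates every input of the pipeline plus a ground-truth manifest:
#'
#' * expression: per gene one log-normal baseline mean, per sample
#'   independent log-scale noise; the member genes of the planted pathways
#'   have their expectation multiplied by `activationFold` at exactly one
#'   (subject, timepoint) cell — the graft-losing period of the case
#'   subject;
#' * pathways: random (overlapping) member sets, categories a balanced
#'   partition; the planted pathways are drawn from a single category;
#' * PPI: Barabasi-Albert preferential attachment (scale-free, as PPI
#'   degree distributions are), node indices mapped to shuffled gene ids;
#' * hypothesis seeds: the causal hypothesis' seeds are chosen among direct
#'   PPI neighbors of the differentially expressed (planted) genes by
#'   greedy coverage — not the DE genes themselves, so propagation has to
#'   add value over naive overlap; non-causal seed sets are drawn uniformly
#'   from genes outside the DE genes and their 1-hop neighborhood.
#'
#' Identical configs (including `rngSeed`) give identical datasets.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @return List with `expression` (SummarizedExperiment), `pathways`
#'   ([PathwayDB-class]), `ppi` (igraph), `seeds` (named list), `truth`
#'   (list: `activated_pathways`, `causal_hypothesis`, `de_genes`).
#' @export
simulateGraftLossDataset <- function(config = simulationConfig()) {
    cfg <- validateSimulationConfig(config)
    set.seed(cfg$rngSeed)
    genes <- sprintf("g%05d", seq_len(cfg$nGenes))

    ## pathway collection: balanced category partition, overlapping members
    pids <- sprintf("pw%04d", seq_len(cfg$nPathways))
    cats <- sprintf("category_%02d", seq_len(cfg$nCategories))
    pcat <- sample(rep(cats, length.out = cfg$nPathways))
    sizes <- sample(seq(cfg$pathwaySizeRange[1], cfg$pathwaySizeRange[2]),
                    cfg$nPathways, replace = TRUE)
    members <- lapply(sizes, function(k) sample(genes, k))
    db <- PathwayDB(pids, paste("Pathway", pids), pcat, members)

    ## planted activated pathways, concentrated in one category
    if (is.numeric(cfg$activatedPathways) &&
        length(cfg$activatedPathways) == 1L) {
        k <- as.integer(cfg$activatedPathways)
        eligible <- names(which(table(pcat) >= k))
        if (length(eligible) == 0L)
            stop("no category has enough pathways to plant the activation")
        host <- sample(eligible, 1)
        activated <- sample(pids[pcat == host], k)
    } else {
        activated <- as.character(cfg$activatedPathways)
        if (!all(activated %in% pids))
            stop("activatedPathways ids not in the generated database")
    }
    deGenes <- sort(unique(unlist(geneSets(db)[activated])))

    ## expression: gene baseline + sample noise, fold on the activated cell
    design <- expand.grid(timepoint = cfg$timepoints,
                          subject = cfg$subjects,
                          stringsAsFactors = FALSE)[, c("subject", "timepoint")]
    mu <- rnorm(cfg$nGenes, cfg$baselineLogmean, cfg$baselineLogsd)
    vals <- vapply(seq_len(nrow(design)), function(j)
        exp(mu + rnorm(cfg$nGenes, 0, cfg$noiseLogsd)), numeric(cfg$nGenes))
    rownames(vals) <- genes
    actCol <- which(design$subject == cfg$activationSubject &
                    design$timepoint == cfg$activationTimepoint)
    vals[deGenes, actCol] <- vals[deGenes, actCol] * cfg$activationFold
    se <- ExpressionSE(vals, design$subject, design$timepoint)

    ## scale-free PPI over all genes: preferential attachment for the
    ## global topology, plus one random spanning path through each
    ## pathway's members so pathways are cohesive modules in the network
    ## (as functional modules are in curated interactomes)
    g <- igraph::sample_pa(cfg$nGenes, m = cfg$ppiEdgesPerNode,
                           directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sample(genes)
    intra <- unlist(lapply(members, function(m) {
        p <- sample(m)
        rbind(p[-length(p)], p[-1])
    }))
    g <- igraph::simplify(igraph::add_edges(g, intra))

    ## hypothesis seeds
    seeds <- vector("list", cfg$nHypotheses)
    names(seeds) <- cfg$hypothesisNames
    av <- igraph::adjacent_vertices(g, deGenes)
    nbrs <- setdiff(unique(unlist(lapply(av, function(v) v$name))), deGenes)
    for (i in seq_len(cfg$nHypotheses)) {
        sz <- cfg$seedSetSizes[i]
        if (i == cfg$causalHypothesisIndex) {
            seeds[[i]] <- greedyNeighborCover(g, deGenes, nbrs, sz)
        } else {
            pool <- setdiff(genes, union(deGenes, nbrs))
            seeds[[i]] <- sort(sample(pool, sz))
        }
    }

    list(expression = se, pathways = db, ppi = g, seeds = seeds,
         truth = list(activated_pathways = sort(activated),
                      causal_hypothesis =
                          cfg$hypothesisNames[cfg$causalHypothesisIndex],
                      de_genes = deGenes),
         config = cfg)
}

## greedy max-coverage with a sqrt-degree penalty: pick non-DE neighbors
## covering the most uncovered DE genes per unit of connectivity (so the
## chosen seeds are DE-specific, not generic hubs), ties broken by gene id
greedyNeighborCover <- function(g, deGenes, candidates, size) {
    adj <- igraph::adjacent_vertices(g, candidates)
    coverAll <- lapply(adj, function(v) intersect(v$name, deGenes))
    names(coverAll) <- candidates
    dg <- igraph::degree(g)[candidates]
    greedy <- function(penalized) {
        cover <- coverAll
        chosen <- character(0)
        uncovered <- deGenes
        for (s in seq_len(size)) {
            gain <- vapply(cover,
                           function(cv) length(intersect(cv, uncovered)), 1L)
            score <- if (penalized) gain / sqrt(dg[names(cover)]) else gain
            best <- names(cover)[order(-score, names(cover))][1]
            chosen <- c(chosen, best)
            uncovered <- setdiff(uncovered, cover[[best]])
            cover[[best]] <- NULL
            if (length(cover) == 0L) break
        }
        list(chosen = sort(chosen),
             covered = length(deGenes) - length(uncovered))
    }
    # degree-penalized pick for specificity; fall back to raw coverage
    # when it cannot reach half of the DE genes
    res <- greedy(penalized = TRUE)
    if (res$covered < length(deGenes) / 2) {
        alt <- greedy(penalized = FALSE)
        if (alt$covered > res$covered) res <- alt
    }
    res$chosen
}
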