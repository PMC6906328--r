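test_that("identical configs give bitwise-identical datasets", {
    ds1 <- simulateGraftLossDataset(smallSimConfig(11))
    ds2 <- simulateGraftLossDataset(smallSimConfig(11))
    expect_identical(SummarizedExperiment::assay(ds1$expression),
                     SummarizedExperiment::assay(ds2$expression))
    expect_identical(igraph::as_edgelist(ds1$ppi),
                     igraph::as_edgelist(ds2$ppi))
    expect_identical(ds1$seeds, ds2$seeds)
    expect_identical(ds1$truth, ds2$truth)
    ds3 <- simulateGraftLossDataset(smallSimConfig(12))
    expect_false(identical(SummarizedExperiment::assay(ds1$expression),
                           SummarizedExperiment::assay(ds3$expression)))
})

test_that("generated data satisfy the declared structural invariants", {
    ds <- simulateGraftLossDataset(smallSimConfig(21))
    expect_true(all(SummarizedExperiment::assay(ds$expression) >= 0))
    expect_true(all(ds$truth$activated_pathways %in% pathwayIds(ds$pathways)))
    expect_setequal(ds$truth$de_genes,
                    unique(unlist(geneSets(ds$pathways)[
                        ds$truth$activated_pathways])))
    # planted pathways share one category so enrichment is recoverable
    expect_length(unique(pathwayCategories(ds$pathways)[
        ds$truth$activated_pathways]), 1)
    # 2 subjects x 4 timepoints design
    cd <- SummarizedExperiment::colData(ds$expression)
    expect_equal(dim(table(cd$subject, cd$timepoint)), c(2, 4))
    expect_true(all(table(cd$subject, cd$timepoint) == 1))
})

test_that("activation multiplies expression expectation by the configured fold", {
    ds <- simulateGraftLossDataset(smallSimConfig(31, activationFold = 4))
    m <- SummarizedExperiment::assay(ds$expression)
    de <- ds$truth$de_genes
    lr <- log2(m[de, "case_t3"] / m[de, "case_t2"])
    # per-gene log2 ratio is log2(4) = 2 plus zero-mean noise
    expect_lt(abs(mean(lr) - 2), 3 * sd(lr) / sqrt(length(de)) + 0.05)
    # a fold of exactly 1 marks the DE genes but leaves expectations flat
    ds0 <- simulateGraftLossDataset(smallSimConfig(31, activationFold = 1))
    m0 <- SummarizedExperiment::assay(ds0$expression)
    lr0 <- log2(m0[ds0$truth$de_genes, "case_t3"] /
                m0[ds0$truth$de_genes, "case_t2"])
    expect_lt(abs(mean(lr0)), 3 * sd(lr0) / sqrt(length(lr0)) + 0.05)
    expect_gt(length(ds0$truth$de_genes), 0)
})

test_that("preferential-attachment PPI is heavy-tailed and covers all genes", {
    ds <- simulateGraftLossDataset(
        simulationConfig(nGenes = 600, nPathways = 20, nCategories = 4,
                         pathwaySizeRange = c(5, 10), ppiEdgesPerNode = 3,
                         rngSeed = 5))
    degs <- igraph::degree(ds$ppi)
    expect_equal(igraph::vcount(ds$ppi), 600)
    expect_gte(max(degs), 3 * median(degs))
    expect_equal(sum(igraph::which_loop(ds$ppi)), 0)
})

test_that("causal seeds sit one hop from the DE genes, non-causal ones far away", {
    ds <- simulateGraftLossDataset(simulationConfig(
        nGenes = 1000, nPathways = 30, nCategories = 6,
        pathwaySizeRange = c(8, 15), ppiEdgesPerNode = 6, rngSeed = 41))
    causal <- ds$seeds[[ds$truth$causal_hypothesis]]
    de <- ds$truth$de_genes
    expect_false(any(causal %in% de))
    nb <- unique(unlist(lapply(
        igraph::adjacent_vertices(ds$ppi, causal), function(v) v$name)))
    expect_gte(sum(de %in% nb), length(de) / 2)
    forbidden <- union(de, unique(unlist(lapply(
        igraph::adjacent_vertices(ds$ppi, de), function(v) v$name))))
    for (nm in setdiff(names(ds$seeds), ds$truth$causal_hypothesis))
        expect_length(intersect(ds$seeds[[nm]], forbidden), 0)
    expect_equal(unname(lengths(ds$seeds)), c(10L, 9L, 8L, 10L, 9L))
})

test_that("infeasible configurations are rejected", {
    expect_error(simulationConfig(nGenes = 20, pathwaySizeRange = c(10, 50)),
                 "infeasible")
    expect_error(simulationConfig(pathwaySizeRange = c(2, 10)), ">= 3")
    expect_error(smallSimConfig(1, hypothesisNames = rep("h", 5)),
                 "duplicate")
    expect_error(smallSimConfig(1, timepoints = c("t1", "t1", "t2", "t3")),
                 "unique")
    expect_error(smallSimConfig(1, activationTimepoint = "t9"), "design")
})

test_that("a written dataset round-trips losslessly through the io layer", {
    ds <- simulateGraftLossDataset(smallSimConfig(51))
    dir <- withr::local_tempdir()
    paths <- writeGraftLossDataset(ds, dir)
    se2 <- readExpression(paths[["expression"]])
    expect_equal(SummarizedExperiment::assay(se2),
                 SummarizedExperiment::assay(ds$expression))
    expect_equal(length(readLines(paths[["pathways"]])),
                 length(ds$pathways))
    db2 <- readPathwayGMT(paths[["pathways"]])
    expect_identical(geneSets(db2), geneSets(ds$pathways))
    expect_identical(pathwayCategories(db2),
                     pathwayCategories(ds$pathways))
    ppi2 <- readPPIEdgeList(paths[["ppi"]])
    expect_equal(igraph::vcount(ppi2),
                 sum(igraph::degree(ds$ppi) > 0))
    expect_equal(igraph::ecount(ppi2), igraph::ecount(ds$ppi))
    seeds2 <- readSeedLists(paths[["seeds"]])
    expect_identical(seeds2[names(ds$seeds)], ds$seeds)
    truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
    expect_identical(truth$causal_hypothesis, ds$truth$causal_hypothesis)
    expect_setequal(truth$activated_pathways, ds$truth$activated_pathways)
})
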