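test_that("DEG profile ranks descending with mid-ranks and applies the filter", {
    m <- rbind(g1 = c(1, 4), g2 = c(1, 2), g3 = c(1, 1),
               g4 = c(0.99, 8), g5 = c(1, 2))
    se <- toySE(m)
    deg <- buildDEGProfile(se, c("case", "t3"), c("case", "t2"))
    expect_false("g4" %in% deg$gene)  # 0.99 in control sample -> excluded
    expect_equal(deg$rank[deg$gene == "g1"], 1)
    expect_equal(deg$rank[deg$gene == "g2"], 2.5)  # tie with g5
    expect_equal(deg$rank[deg$gene == "g5"], 2.5)
    expect_equal(deg$rank[deg$gene == "g3"], 4)
    # absolute ranking puts a strong down-regulation first
    m2 <- rbind(a = c(8, 1), b = c(1, 2), c = c(1, 1))
    dega <- buildDEGProfile(toySE(m2), c("case", "t3"), c("case", "t2"),
                            rankBy = "absolute")
    expect_equal(dega$gene[dega$rank == 1], "a")  # |log2FC| = 3
    expect_error(buildDEGProfile(toySE(rbind(a = c(0.1, 0.2))),
                                 c("case", "t3"), c("case", "t2")),
                 "no gene survives")
})

test_that("propagation respects seed dominance and graph symmetry", {
    two <- igraph::graph_from_edgelist(cbind("A", "B"), directed = FALSE)
    pr <- propagateSeeds(two, "A", restartProb = 0.3)
    expect_gt(pr$scores[["A"]], pr$scores[["B"]])
    k5 <- igraph::make_full_graph(5)
    igraph::V(k5)$name <- LETTERS[1:5]
    prK <- propagateSeeds(k5, "A")
    expect_equal(var(prK$scores[c("B", "C", "D", "E")]), 0)
    expect_gt(prK$scores[["A"]], prK$scores[["B"]])
    # unmapped seeds are dropped with a warning; all-unmapped is an error
    expect_warning(pr2 <- propagateSeeds(two, c("A", "zz")), "dropped")
    expect_equal(pr2$seeds_used, "A")
    expect_error(suppressWarnings(propagateSeeds(two, "zz")), "no seed")
    expect_error(propagateSeeds(two, "A", restartProb = 1.5), "restartProb")
})

test_that("iterative propagation matches the direct linear solve", {
    set.seed(5)
    for (rep in 1:12) {
        n <- sample(5:30, 1)
        g <- igraph::sample_gnp(n, 0.3)
        igraph::V(g)$name <- paste0("v", seq_len(n))
        seeds <- sample(igraph::V(g)$name, sample(1:3, 1))
        for (norm in c("symmetric", "column")) {
            it <- propagateSeeds(g, seeds, restartProb = 0.5, tol = 1e-12,
                                 normalization = norm)
            direct <- rwrSolveOracle(g, seeds, 0.5, norm)
            expect_lt(max(abs(it$scores - direct[names(it$scores)])), 1e-8)
        }
    }
})

test_that("column-stochastic propagation conserves probability mass", {
    set.seed(9)
    g <- igraph::sample_pa(80, m = 2, directed = FALSE)
    igraph::V(g)$name <- paste0("v", 1:80)
    pr <- propagateSeeds(g, c("v1", "v5", "v9"), normalization = "column",
                         tol = 1e-12)
    expect_equal(sum(pr$scores), 1, tolerance = 1e-9)
    expect_true(all(pr$scores >= 0))
    # ranks descend with score
    ord <- order(-pr$scores)
    expect_true(all(diff(pr$rank[ord]) >= 0))
})

test_that("rank correlation reproduces hand-computed coefficients", {
    mk <- function(scores) list(scores = scores,
                                rank = rank(-scores, ties.method = "average"))
    deg <- data.frame(gene = paste0("g", 1:4), log2fc = c(4, 3, 2, 1),
                      rank = c(1, 2, 3, 4))
    same <- mk(setNames(c(40, 30, 20, 10), paste0("g", 1:4)))
    expect_equal(rankCorrelation(same, deg)$coefficient, 1)
    rev <- mk(setNames(c(10, 20, 30, 40), paste0("g", 1:4)))
    expect_equal(rankCorrelation(rev, deg)$coefficient, -1)
    # prop ranks {1,2,3,4} against deg ranks {2,1,4,3}: Pearson = 0.6
    deg2 <- data.frame(gene = paste0("g", 1:4), log2fc = c(3, 4, 1, 2),
                       rank = c(2, 1, 4, 3))
    expect_equal(rankCorrelation(same, deg2)$coefficient, 0.6)
    expect_equal(rankCorrelation(same, deg2)$parametric_p,
                 stats::cor.test(1:4, c(2, 1, 4, 3))$p.value)
    expect_error(rankCorrelation(mk(setNames(1:2, c("g1", "g2"))), deg),
                 "at least 3")
})

test_that("top-k correlation restricts, re-ranks and breaks ties by gene id", {
    scores <- setNames(c(0.5, 0.4, 0.3, 0.2, 0.1), paste0("g", 1:5))
    prop <- list(scores = scores, rank = rank(-scores))
    deg <- data.frame(gene = paste0("g", 1:5), log2fc = 5:1,
                      rank = c(2, 1, 3, 5, 4))
    expect_equal(topKCorrelation(prop, deg, 5)$coefficient,
                 rankCorrelation(prop, deg)$coefficient)
    # hand enumeration at k = 3: genes g1,g2,g3; prop ranks 1,2,3 vs deg
    # re-ranked 2,1,3 -> Pearson 0.5
    expect_equal(topKCorrelation(prop, deg, 3)$coefficient,
                 cor(c(1, 2, 3), c(2, 1, 3)))
    expect_error(topKCorrelation(prop, deg, 9), "exceeds")
    # boundary tie: g3 and g4 share a score; gene id decides who enters
    s2 <- setNames(c(0.5, 0.4, 0.3, 0.3, 0.1), paste0("g", 1:5))
    prop2 <- list(scores = s2, rank = rank(-s2, ties.method = "average"))
    r1 <- topKCorrelation(prop2, deg, 3)
    r2 <- topKCorrelation(prop2, deg, 3)
    expect_identical(r1, r2)
    expect_equal(r1$coefficient, cor(c(1, 2, 3), c(2, 1, 3)))  # g3 over g4
})

test_that("the empirical p formula is the strict exceedance fraction", {
    expect_equal(empiricalP(c(rep(0, 990), rep(2, 10)), 1), 0.010)
    expect_equal(empiricalP(rep(0, 100), 1), 0)    # reference beats all
    expect_equal(empiricalP(rep(2, 100), 1), 1)    # all beat the reference
    expect_equal(empiricalP(rep(1, 100), 1), 0)    # ties do not exceed
    expect_equal(empiricalP(c(rep(0, 99), 2), 1, correction = "add_one"),
                 2 / 101)
})

test_that("simulation-based empirical p is deterministic and lattice-valued", {
    set.seed(2)
    g <- igraph::sample_pa(60, m = 2, directed = FALSE)
    igraph::V(g)$name <- paste0("v", 1:60)
    deg <- data.frame(gene = paste0("v", 1:60), log2fc = rnorm(60),
                      rank = rank(-rnorm(60)))
    e1 <- empiricalPvalue(g, deg, seedSize = 4, referenceCoeff = 0.2,
                          nSim = 25, rngSeed = 10)
    e2 <- empiricalPvalue(g, deg, seedSize = 4, referenceCoeff = 0.2,
                          nSim = 25, rngSeed = 10)
    expect_identical(e1, e2)
    expect_true(e1$empirical_p %in% ((0:25) / 25))
    expect_length(e1$random_coefficients, 25)
    expect_error(empiricalPvalue(g, deg, 4, 0.2, nSim = 5,
                                 sampler = "degree_matched"),
                 "reference seed set")
    e3 <- empiricalPvalue(g, deg, seedSize = 4, referenceCoeff = 0.2,
                          nSim = 10, sampler = "degree_matched",
                          referenceSeeds = c("v1", "v2", "v30", "v55"),
                          rngSeed = 3)
    expect_true(e3$empirical_p %in% ((0:10) / 10))
})

test_that("hypothesis evaluation sorts by coefficient and honors identical seeds", {
    set.seed(4)
    g <- igraph::sample_pa(80, m = 2, directed = FALSE)
    igraph::V(g)$name <- paste0("v", 1:80)
    lfc <- rnorm(80)
    deg <- data.frame(gene = paste0("v", 1:80), log2fc = lfc,
                      rank = rank(-lfc))
    seeds <- list(h1 = c("v3", "v7", "v11"), h2 = c("v3", "v7", "v11"))
    ev <- evaluateHypotheses(g, deg, seeds, nSim = 10, rngSeed = 6)
    tab <- hypothesisTable(ev)
    expect_equal(tab$coefficient[tab$hypothesis == "h1"],
                 tab$coefficient[tab$hypothesis == "h2"])
    expect_true(all(diff(tab$coefficient) <= 0))
    single <- evaluateHypotheses(g, deg, list(only = c("v1", "v2", "v4")),
                                 nSim = 5, rngSeed = 1)
    expect_equal(nrow(hypothesisTable(single)), 1)
    expect_error(evaluateHypotheses(g, deg, list(), nSim = 5), "at least one")
    expect_error(evaluateHypotheses(g, deg,
                                    setNames(seeds, c("h", "h")), nSim = 5),
                 "unique names")
})
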