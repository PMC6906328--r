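# Independent oracles used to cross-check the package implementations.
# They deliberately avoid the code paths (and where possible the libraries)
# they validate.

# hand-rolled BFS hop distances from `start` over an adjacency list;
# unreachable nodes get Inf
bfsDistancesOracle <- function(adj, start) {
    n <- length(adj)
    dist <- rep(Inf, n)
    dist[start] <- 0
    queue <- c(start)
    while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
            if (is.infinite(dist[w])) {
                dist[w] <- dist[v] + 1
                queue <- c(queue, w)
            }
        }
    }
    dist
}

# Wasserman-Faust closeness of every node from the BFS oracle
closenessOracle <- function(adj) {
    n <- length(adj)
    vapply(seq_len(n), function(v) {
        d <- bfsDistancesOracle(adj, v)[-v]
        r <- sum(is.finite(d))
        if (r == 0) return(0)
        (r / (n - 1)) * (r / sum(d[is.finite(d)]))
    }, numeric(1))
}

igraphToAdjList <- function(g) {
    n <- igraph::vcount(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    adj <- vector("list", n)
    for (i in seq_len(nrow(el))) {
        a <- el[i, 1]; b <- el[i, 2]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    adj
}

# exhaustive hypergeometric tail P(X >= a) by log-binomial enumeration
hyperTailOracle <- function(a, b, c_, d) {
    m1 <- a + b                      # selected margin
    xs <- seq(a, min(m1, a + c_))    # feasible in-category counts
    if (length(xs) == 0 || a > min(m1, a + c_)) return(0)
    sum(exp(lchoose(a + c_, xs) + lchoose(b + d, m1 - xs) -
            lchoose(a + b + c_ + d, m1)))
}

# RWR fixed point by direct dense linear solve r (I - (1-r) W)^-1 s0
rwrSolveOracle <- function(ppi, seeds, r, normalization = "symmetric") {
    A <- as.matrix(igraph::as_adjacency_matrix(ppi))
    deg <- colSums(A)
    inv <- ifelse(deg > 0, 1 / deg, 0)
    W <- if (normalization == "symmetric")
        diag(sqrt(inv)) %*% A %*% diag(sqrt(inv))
    else A %*% diag(inv)
    genes <- igraph::V(ppi)$name
    s0 <- setNames(numeric(length(genes)), genes)
    s0[seeds] <- 1 / length(seeds)
    setNames(as.numeric(r * solve(diag(length(genes)) - (1 - r) * W, s0)),
             genes)
}

# enumeration of k-subsets via bit masks (independent of utils::combn):
# exact competitive-test tail fraction #{subset mean >= observed}/C(n,k)
exactTailOracle <- function(x, memberIdx) {
    n <- length(x)
    k <- length(memberIdx)
    obs <- mean(x[memberIdx])
    total <- 0L; ge <- 0L
    for (mask in seq_len(2^n) - 1L) {
        bits <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
        if (length(bits) != k) next
        total <- total + 1L
        if (mean(x[bits]) >= obs - 1e-12) ge <- ge + 1L
    }
    ge / total
}

# small labelled PPI triangle-plus-tail used across tests
toyPPI <- function() {
    igraph::graph_from_edgelist(
        cbind(c("a", "a", "b", "c", "d"),
              c("b", "c", "c", "d", "e")), directed = FALSE)
}

# tiny expression set: columns case_t2, case_t3[, control_t2, control_t3]
toySE <- function(mat) {
    nc <- ncol(mat)
    ExpressionSE(mat,
                 subject = rep(c("case", "control"), each = 2)[seq_len(nc)],
                 timepoint = rep(c("t2", "t3"), 2)[seq_len(nc)])
}

# minimal activity-result data.frame for selectGLPAPs tests
activityRow <- function(id, p, direction = "up", comparison = "cmp",
                        testable = TRUE) {
    data.frame(pathway_id = id, name = id, category = "cat",
               comparison = comparison, n_used = 5L,
               statistic = ifelse(direction == "up", 1, -1),
               direction = direction, p_value = p, testable = testable)
}

smallSimConfig <- function(seed, ...) {
    simulationConfig(nGenes = 400, nPathways = 30, nCategories = 6,
                     pathwaySizeRange = c(5, 12), ppiEdgesPerNode = 3,
                     rngSeed = seed, ...)
}
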