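# Independent oracles and small fixture builders used across the suite.

# Triple-loop topological overlap oracle (independent of the package's
# matrix-algebra implementation).
tomOracle <- function(A) {
    diag(A) <- 1
    n <- nrow(A)
    TOM <- matrix(0, n, n)
    k <- numeric(n)
    for (i in seq_len(n)) k[i] <- sum(A[i, -i])
    for (i in seq_len(n)) {
        TOM[i, i] <- 1
        for (j in seq_len(n)) {
            if (i == j) next
            l <- 0
            for (u in seq_len(n))
                if (u != i && u != j) l <- l + A[i, u] * A[u, j]
            TOM[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
        }
    }
    TOM
}

# Rank-based AUROC (Mann-Whitney identity).
aurocSimple <- function(score, label) {
    r <- rank(score)
    n1 <- sum(label)
    n0 <- sum(!label)
    (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    expd <- si * sj / n2
    (sij - expd) / ((si + sj) / 2 - expd)
}

# Standard cluster purity of a labeling against ground-truth classes:
# sum over clusters of the majority class count, over total.
clusterPurity <- function(clusters, classes) {
    tab <- table(clusters, classes)
    sum(apply(tab, 1, max)) / sum(tab)
}

# A Trajectory object around a given pseudotime vector (for tests that
# need pseudotime without running inference).
mkTrajectory <- function(pt) {
    pt <- (pt - min(pt)) / (max(pt) - min(pt))
    n <- length(pt)
    methods::new("Trajectory", pseudotime = pt,
                 state = stats::setNames(rep("1", n), names(pt)),
                 rootCell = names(pt)[which.min(pt)],
                 treeEdges = matrix(integer(0), 0, 2),
                 centroids = matrix(0, 1, 2),
                 embedding = matrix(0, n, 2))
}

# A MesoCounts from a plain matrix with no mitochondrial genes.
mkCounts <- function(cts) MesoCounts(cts, mito = character(0))

# Well-separated 2-D blobs: returns embedding matrix and memberships.
mkBlobs <- function(k = 8, per = 40, sep = 30, seed = 1) {
    set.seed(seed)
    centers <- cbind(sep * cos(2 * pi * seq_len(k) / k),
                     sep * sin(2 * pi * seq_len(k) / k))
    emb <- do.call(rbind, lapply(seq_len(k), function(i)
        cbind(stats::rnorm(per, centers[i, 1], 0.5),
              stats::rnorm(per, centers[i, 2], 0.5))))
    rownames(emb) <- sprintf("b%03d", seq_len(k * per))
    list(embedding = emb, membership = rep(seq_len(k), each = per))
}

# Per-offset brute-force PWM scan on both strands of one sequence.
scanOracle <- function(pwm, seqChr, threshold) {
    lo <- log2((pwm@mat + 1e-9) / rep(pwm@background + 1e-9,
                                      each = nrow(pwm@mat)))
    w <- nrow(pwm@mat)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    bases <- strsplit(seqChr, "")[[1]]
    L <- length(bases)
    hits <- data.frame(offset = integer(), strand = character(),
                       score = numeric())
    scoreAt <- function(bs) {
        s <- 0
        for (p in seq_len(w)) {
            b <- bs[p]
            s <- s + if (b %in% c("A", "C", "G", "T"))
                lo[p, match(b, c("A", "C", "G", "T"))] else 0
        }
        s
    }
    for (o in seq_len(L - w + 1L)) {
        fw <- bases[o:(o + w - 1L)]
        s1 <- scoreAt(fw)
        if (s1 >= threshold)
            hits <- rbind(hits, data.frame(offset = o, strand = "+",
                                           score = s1))
        rv <- rev(unname(comp[fw]))
        s2 <- scoreAt(rv)
        if (s2 >= threshold)
            hits <- rbind(hits, data.frame(offset = o, strand = "-",
                                           score = s2))
    }
    hits
}

# Unordered pair keys for edge-set comparisons.
pairKeys <- function(a, b) sort(paste(pmin(a, b), pmax(a, b)))
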