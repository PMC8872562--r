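# Pseudotime: MST-backbone trajectory inference, marker-based
# orientation, NB spline tests for pseudotime-dynamic genes, and
# profile clustering of the dynamic genes.

#' Infer a pseudotime trajectory
#'
#' Embeds cells (log-normalized, gene-scaled, PCA to `nComponents`),
#' clusters them into centroids by k-means, learns a minimum spanning
#' tree over the centroids, projects every cell onto its nearest tree
#' edge, and reads pseudotime off as the geodesic distance from a
#' provisional root (one end of the tree diameter), min-max normalized
#' to `[0, 1]`. Branch ("state") labels follow the maximal unbranched
#' segments of the tree. Use [orientTrajectory()] to fix the biological
#' direction.
#'
#' @param x a [MesoCounts-class] object.
#' @param genes genes to use (e.g. dynamic or highly variable genes);
#'   default all genes.
#' @param nComponents dimensionality of the reduced space (default 2).
#' @param nCentroids number of tree centroids; default
#'   `max(4, min(30, round(sqrt(nCells))))`.
#' @param seed RNG seed (k-means initialization).
#' @return A [Trajectory-class] object.
#' @export
inferPseudotime <- function(x, genes = rownames(x), nComponents = 2,
                            nCentroids = NULL, seed = 1) {
    if (ncol(x) < 10) stop("need at least 10 cells")
    e <- logNormCounts(x)[intersect(genes, rownames(x)), , drop = FALSE]
    es <- t(scale(t(e)))
    es[!is.finite(es)] <- 0
    if (all(abs(es) < 1e-12))
        stop("degenerate trajectory: expression matrix is constant")
    set.seed(seed)
    pc <- stats::prcomp(t(es), center = TRUE)
    emb <- pc$x[, seq_len(min(nComponents, ncol(pc$x))), drop = FALSE]
    n <- nrow(emb)
    if (is.null(nCentroids))
        nCentroids <- max(4L, min(30L, round(sqrt(n))))
    km <- stats::kmeans(emb, centers = min(nCentroids, n - 1L),
                        nstart = 5, iter.max = 50)
    cen <- km$centers
    nc <- nrow(cen)

    # MST over centroids
    dmat <- as.matrix(stats::dist(cen))
    g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    el <- igraph::as_edgelist(mst, names = FALSE)
    storage.mode(el) <- "integer"

    # provisional root: one end of the weighted tree diameter
    dia <- igraph::get_diameter(mst)
    root <- as.integer(dia[1])
    dRoot <- igraph::distances(mst, v = root)[1, ]

    # branch labels: split tree at nodes of degree > 2
    deg <- igraph::degree(mst)
    branchOf <- integer(igraph::ecount(mst))
    keepE <- el[deg[el[, 1]] <= 2 & deg[el[, 2]] <= 2, , drop = FALSE]
    segG <- igraph::graph_from_edgelist(keepE, directed = FALSE)
    segG <- igraph::add_vertices(segG, max(0, nc - igraph::vcount(segG)))
    segMemb <- igraph::components(segG)$membership
    for (k in seq_len(nrow(el)))
        branchOf[k] <- min(segMemb[el[k, 1]], segMemb[el[k, 2]])

    # project each cell onto the nearest tree edge
    pt <- numeric(n)
    state <- character(n)
    for (i in seq_len(n)) {
        p <- emb[i, ]
        best <- Inf; bd <- 0; bb <- 1L
        for (k in seq_len(nrow(el))) {
            u <- el[k, 1]; v <- el[k, 2]
            a <- cen[u, ]; b <- cen[v, ]
            ab <- b - a
            L2 <- sum(ab^2)
            tt <- if (L2 < 1e-24) 0 else
                min(1, max(0, sum((p - a) * ab) / L2))
            q <- a + tt * ab
            d2 <- sum((p - q)^2)
            if (d2 < best) {
                best <- d2
                L <- sqrt(L2)
                bd <- if (dRoot[v] >= dRoot[u]) dRoot[u] + tt * L
                      else dRoot[v] + (1 - tt) * L
                bb <- branchOf[k]
            }
        }
        pt[i] <- bd
        state[i] <- as.character(bb)
    }
    rng <- range(pt)
    if (diff(rng) < 1e-12)
        stop("degenerate trajectory: all cells project to one point")
    pt <- (pt - rng[1]) / diff(rng)
    names(pt) <- rownames(emb)
    names(state) <- rownames(emb)
    methods::new("Trajectory", pseudotime = pt, state = state,
                 rootCell = names(pt)[which.min(pt)],
                 treeEdges = el, centroids = unname(cen),
                 embedding = unname(emb))
}

#' Reverse a trajectory
#'
#' Maps pseudotime `p` to `1 - p` exactly, keeping tree and states.
#'
#' @param t a [Trajectory-class] object.
#' @return the reversed [Trajectory-class].
#' @export
reverseTrajectory <- function(t) {
    pt <- 1 - t@pseudotime
    methods::new("Trajectory", pseudotime = pt, state = t@state,
                 rootCell = names(pt)[which.min(pt)],
                 treeEdges = t@treeEdges, centroids = t@centroids,
                 embedding = t@embedding)
}

#' Orient a trajectory with origin markers
#'
#' Chooses the trajectory direction so that the mean expression of the
#' supplied origin markers, averaged over the lowest-pseudotime decile of
#' cells, is minimized. This implements the standard rooting logic for
#' maturation trajectories: marker genes known to be lowest at the organ
#' base (e.g. the C4 photosynthesis panel AspAT, NADP-MDH, PPDK, CA,
#' PEPC) pin the root at the young end.
#'
#' @param t a [Trajectory-class] object.
#' @param x the [MesoCounts-class] the trajectory was inferred from.
#' @param markers character vector of origin marker genes (expected to
#'   increase along the trajectory).
#' @param decile fraction of cells defining each trajectory end.
#' @param tol ambiguity tolerance on the end-to-end marker difference.
#' @return the oriented [Trajectory-class].
#' @export
orientTrajectory <- function(t, x, markers, decile = 0.1, tol = 1e-8) {
    markers <- intersect(markers, rownames(x))
    if (length(markers) == 0) stop("no origin markers present")
    e <- logNormCounts(x)[markers, names(t@pseudotime), drop = FALSE]
    if (all(e == 0)) stop("origin markers are not expressed")
    lowEnd <- function(pt) {
        q <- stats::quantile(pt, decile)
        mean(e[, pt <= q, drop = FALSE])
    }
    fwd <- lowEnd(t@pseudotime)
    rev <- lowEnd(1 - t@pseudotime)
    if (abs(fwd - rev) < tol)
        stop("ambiguous orientation: markers are flat at both ends")
    if (fwd <= rev) t else reverseTrajectory(t)
}

#' Test genes for pseudotime-dependent expression
#'
#' For each gene whose mean size-factor-normalized expression exceeds
#' `minMean`, fits a negative-binomial GLM with a natural cubic spline of
#' pseudotime (`dfSpline` degrees of freedom, library-size offset)
#' against an intercept-only null, and reports the likelihood-ratio
#' statistic with a chi-squared p-value on `dfSpline` degrees of freedom.
#' The NB size parameter is estimated per gene under the null. P-values
#' are Benjamini-Hochberg adjusted across tested genes; genes whose fit
#' fails are flagged and excluded from the adjustment.
#'
#' @param x a [MesoCounts-class] object.
#' @param t a [Trajectory-class] covering the cells of `x`.
#' @param minMean expression cutoff defining "expressed" genes
#'   (default 0.1, on size-factor-normalized counts).
#' @param dfSpline spline degrees of freedom (default 3).
#' @param qThreshold significance cutoff stored in the result
#'   (default 0.01).
#' @return data.frame per gene: `gene`, `meanExpr`, `tested`, `lrtStat`,
#'   `p`, `q`, `significant`, `failed`, `cluster` (`"none"`, filled by
#'   [clusterGeneProfiles()]).
#' @export
testDynamicGenes <- function(x, t, minMean = 0.1, dfSpline = 3,
                             qThreshold = 0.01) {
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    pt <- t@pseudotime[colnames(cts)]
    if (anyNA(pt)) stop("pseudotime missing for some cells")
    sf <- sizeFactors_(cts)
    norm <- sweep(cts, 2, sf, "/")
    meanExpr <- rowMeans(norm)
    tested <- meanExpr > minMean
    spl <- splines::ns(pt, df = dfSpline)
    off <- log(sf)
    res <- data.frame(gene = rownames(cts), meanExpr = meanExpr,
                      tested = tested, lrtStat = NA_real_, p = NA_real_,
                      q = NA_real_, significant = FALSE, failed = FALSE,
                      cluster = "none", row.names = NULL)
    for (i in which(tested)) {
        y <- cts[i, ]
        fit <- tryCatch({
            null0 <- suppressWarnings(
                MASS::glm.nb(y ~ 1 + offset(off)))
            fam <- MASS::negative.binomial(null0$theta)
            full <- suppressWarnings(
                stats::glm(y ~ spl, family = fam, offset = off))
            null <- suppressWarnings(
                stats::glm(y ~ 1, family = fam, offset = off))
            stat <- max(0, null$deviance - full$deviance)
            c(stat, stats::pchisq(stat, dfSpline, lower.tail = FALSE))
        }, error = function(e) NULL)
        if (is.null(fit)) res$failed[i] <- TRUE
        else {
            res$lrtStat[i] <- fit[1]
            res$p[i] <- fit[2]
        }
    }
    ok <- tested & !res$failed
    res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
    res$significant <- !is.na(res$q) & res$q < qThreshold
    res
}

#' Smoothed pseudotime expression profiles
#'
#' Bins cells into `nBins` equal-width pseudotime bins and averages the
#' log1p size-factor-normalized expression per bin; empty bins are filled
#' by linear interpolation. Deterministic and directly checkable against
#' a by-hand binned mean.
#'
#' @param x a [MesoCounts-class] object.
#' @param t a [Trajectory-class].
#' @param genes genes to profile.
#' @param nBins number of pseudotime bins (default 100).
#' @return genes x nBins matrix.
#' @export
pseudotimeProfiles <- function(x, t, genes, nBins = 100) {
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    pt <- t@pseudotime[colnames(cts)]
    sf <- sizeFactors_(cts)
    e <- log1p(sweep(cts[genes, , drop = FALSE], 2, sf, "/"))
    bin <- pmin(nBins, floor(pt * nBins) + 1L)
    prof <- matrix(NA_real_, length(genes), nBins,
                   dimnames = list(genes, NULL))
    for (b in seq_len(nBins)) {
        i <- bin == b
        if (any(i)) prof[, b] <- rowMeans(e[, i, drop = FALSE])
    }
    t(apply(prof, 1, function(r) {
        if (anyNA(r)) {
            ok <- which(!is.na(r))
            r <- stats::approx(ok, r[ok], xout = seq_along(r),
                               rule = 2)$y
        }
        r
    }))
}

#' Cluster dynamic-gene expression profiles
#'
#' Z-scores each significant gene's binned pseudotime profile,
#' hierarchically clusters the genes (Ward linkage on Euclidean
#' distance) and cuts the tree into `k` clusters. Cluster ids `G1..Gk`
#' are ordered by the pseudotime bin at which each cluster's mean profile
#' peaks, so `G1` peaks earliest.
#'
#' @param dyn result of [testDynamicGenes()].
#' @param x a [MesoCounts-class] object.
#' @param t a [Trajectory-class].
#' @param k number of gene clusters (default 6).
#' @param nBins number of pseudotime bins for smoothing (default 100).
#' @return `dyn` with the `cluster` column filled (`G1..Gk` for
#'   significant genes, `"none"` otherwise); the profile matrix is
#'   attached as attribute `"profiles"`.
#' @export
clusterGeneProfiles <- function(dyn, x, t, k = 6, nBins = 100) {
    sig <- dyn$gene[dyn$significant]
    if (k > length(sig))
        stop("k exceeds the number of significant genes (", length(sig), ")")
    prof <- pseudotimeProfiles(x, t, sig, nBins = nBins)
    z <- t(scale(t(prof)))
    z[!is.finite(z)] <- 0
    hc <- stats::hclust(stats::dist(z), method = "ward.D2")
    grp <- stats::cutree(hc, k = k)
    peak <- vapply(seq_len(k), function(c)
        which.max(colMeans(z[grp == c, , drop = FALSE])), numeric(1))
    ord <- order(peak)
    relab <- integer(k)
    relab[ord] <- seq_len(k)
    lab <- paste0("G", relab[grp])
    dyn$cluster <- "none"
    dyn$cluster[match(sig, dyn$gene)] <- lab
    attr(dyn, "profiles") <- z
    dyn
}
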