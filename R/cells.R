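# Cell-level processing: quality control, highly-variable-gene selection,
# 2-D embedding, Louvain clustering and marker-based annotation.

#' Cluster assignment of cells
#'
#' @slot labels named integer cluster label per cell, contiguous
#'   `0..nClusters-1` with every value used, ordered by cluster size.
#' @slot resolution resolution parameter used.
#' @slot nClusters number of clusters.
#' @aliases ClusterAssignment-class
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
    representation(labels = "integer", resolution = "numeric",
                   nClusters = "integer"))

setValidity("ClusterAssignment", function(object) {
    lv <- sort(unique(object@labels))
    if (!identical(lv, seq_len(object@nClusters) - 1L))
        "labels must cover 0..nClusters-1 with every value used" else TRUE
})

setMethod("show", "ClusterAssignment", function(object) {
    cat("ClusterAssignment:", length(object@labels), "cells in",
        object@nClusters, "clusters (resolution",
        object@resolution, ")\n")
})

#' @describeIn ClusterAssignment named integer label accessor.
#' @param x a `ClusterAssignment`.
#' @export
clusterLabels <- function(x) x@labels

#' Quality-control filtering of cells
#'
#' Flags and removes low-quality cells: a cell fails when its total read
#' count is below `minReads` (strictly less than) or its mitochondrial
#' read ratio exceeds `maxMito` (strictly greater than). Cells exactly at
#' either threshold are retained. The gene set is unchanged.
#'
#' @param x a [MesoCounts-class] object.
#' @param minReads minimum total reads per cell (default 10,000).
#' @param maxMito maximum mitochondrial read ratio (default 0.2).
#' @return list with `counts` (filtered [MesoCounts-class]) and `qc`
#'   (data.frame `cell`, `totalReads`, `mitoRatio`, `pass`, `reason` for
#'   every input cell).
#' @examples
#' sim <- simulateCells(simulateGrn(4, 0.2, seed = 1), nCells = 50,
#'                      nLowq = 5, seed = 1)
#' res <- qcFilter(sim$counts)
#' table(res$qc$pass)
#' @export
qcFilter <- function(x, minReads = 10000, maxMito = 0.2) {
    cts <- SummarizedExperiment::assay(x, "counts")
    total <- Matrix::colSums(cts)
    mito <- Matrix::colSums(cts[mitoMask(x), , drop = FALSE])
    ratio <- ifelse(total > 0, mito / total, 1)
    passReads <- total >= minReads
    passMito <- ratio <= maxMito
    pass <- passReads & passMito
    reason <- rep("", length(total))
    reason[!passReads] <- "reads"
    reason[passReads & !passMito] <- "mito"
    reason[!passReads & !passMito] <- "reads;mito"
    qc <- data.frame(cell = colnames(x), totalReads = as.integer(total),
                     mitoRatio = ratio, pass = pass, reason = reason,
                     row.names = NULL)
    if (!any(pass))
        stop("all cells fail QC (reads: ", sum(!passReads),
             ", mito: ", sum(!passMito), ")")
    list(counts = x[, pass], qc = qc)
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion of their log-normalized
#' expression: genes are placed into 20 equal-frequency mean-expression
#' bins; dispersion is `log(variance/mean)`; dispersions are z-scored
#' within each bin; the top `n` genes are returned. Ties are broken by
#' lexicographic gene id, so the ranking is fully deterministic.
#'
#' @param x a [MesoCounts-class] object.
#' @param n number of genes to return (default 1500, capped at the number
#'   of genes with positive expression only by the error below).
#' @param nBins number of mean bins.
#' @return character vector of `n` gene ids, ranked most variable first.
#' @export
selectHvg <- function(x, n = 1500, nBins = 20) {
    if (n > nrow(x)) stop("n exceeds the number of genes")
    e <- logNormCounts(x)
    mu <- rowMeans(e)
    v <- apply(e, 1, stats::var)
    keep <- mu > 0 & v > 0
    disp <- rep(-Inf, nrow(e))
    names(disp) <- rownames(e)
    dk <- log(v[keep] / mu[keep])
    nb <- max(1L, min(nBins, floor(sum(keep) / 2)))
    bins <- if (nb >= 2)
        cut(rank(mu[keep], ties.method = "first"), breaks = nb,
            labels = FALSE)
    else rep(1L, sum(keep))
    z <- dk
    for (b in unique(bins)) {
        i <- bins == b
        s <- stats::sd(dk[i])
        z[i] <- (dk[i] - mean(dk[i])) / ifelse(is.na(s) || s < 1e-12, 1, s)
    }
    disp[names(z)] <- z
    ord <- order(-disp, names(disp))
    rownames(e)[ord][seq_len(n)]
}

#' Embed cells in two dimensions
#'
#' Log-normalizes, restricts to the supplied variable genes, z-scales
#' genes, computes `nPcs` principal components and reduces them to two
#' dimensions, either with UMAP (via the uwot package, if installed) or
#' by taking the first two principal components (`method = "pca"`; exact
#' and deterministic). The seed fixes the output for either backend.
#'
#' @param x a [MesoCounts-class] object.
#' @param hvg character vector of variable genes.
#' @param nPcs number of principal components (default 25).
#' @param method `"umap"` or `"pca"`.
#' @param nNeighbors UMAP neighborhood size (default 50).
#' @param minDist UMAP minimum distance (default 0.1).
#' @param seed RNG seed.
#' @return cells x 2 coordinate matrix.
#' @export
embedCells <- function(x, hvg, nPcs = 25, method = c("umap", "pca"),
                       nNeighbors = 50, minDist = 0.1, seed = 1) {
    method <- match.arg(method)
    if (length(hvg) == 0) stop("hvg must be non-empty")
    if (nPcs > min(dim(x))) stop("nPcs exceeds min(cells, genes)")
    e <- logNormCounts(x)[hvg, , drop = FALSE]
    es <- t(scale(t(e)))
    es[!is.finite(es)] <- 0
    set.seed(seed)
    pc <- stats::prcomp(t(es), center = TRUE, scale. = FALSE)
    k <- min(nPcs, ncol(pc$x))
    pcs <- pc$x[, seq_len(k), drop = FALSE]
    if (method == "umap" && requireNamespace("uwot", quietly = TRUE)) {
        nn <- min(nNeighbors, nrow(pcs) - 1L)
        emb <- uwot::umap(pcs, n_neighbors = nn, min_dist = minDist,
                          n_threads = 1, n_sgd_threads = 0, seed = seed)
    } else {
        if (method == "umap")
            warning("uwot not available; falling back to PCA-2D")
        emb <- pcs[, 1:2, drop = FALSE]
    }
    emb <- unname(emb[, 1:2, drop = FALSE])
    dimnames(emb) <- list(colnames(x), c("dim1", "dim2"))
    emb
}

#' Cluster cells by Louvain community detection
#'
#' Builds a k-nearest-neighbor graph on the 2-D embedding coordinates and
#' applies modularity-based Louvain community detection at the given
#' resolution. Labels are relabeled to the contiguous range
#' `0..nClusters-1` ordered by decreasing cluster size. Resolution 0.05
#' gives the coarse cell-type clustering; 0.5 the fine clustering used
#' for pseudo-bulk samples.
#'
#' @param embedding cells x 2 coordinate matrix with rownames.
#' @param resolution Louvain resolution.
#' @param k number of nearest neighbors for the graph (default 15).
#' @return A [ClusterAssignment-class] object.
#' @export
clusterCells <- function(embedding, resolution = 0.05, k = 15) {
    n <- nrow(embedding)
    if (n < 2) stop("need at least 2 cells")
    if (all(apply(embedding, 2, stats::sd) < 1e-12)) {
        warning("degenerate embedding (all coordinates identical); ",
                "returning a single cluster")
        labels <- stats::setNames(rep(0L, n), rownames(embedding))
        return(methods::new("ClusterAssignment", labels = labels,
                            resolution = resolution, nClusters = 1L))
    }
    k <- min(k, n - 1L)
    d <- as.matrix(stats::dist(embedding))
    nnIdx <- apply(d, 1, function(r) order(r)[2:(k + 1L)])
    edges <- cbind(rep(seq_len(n), each = k), as.vector(nnIdx))
    edges <- unique(t(apply(edges, 1, sort)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(0)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    memb <- igraph::membership(comm)
    sizes <- sort(table(memb), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
    labels <- stats::setNames(as.integer(relab[as.character(memb)]),
                              rownames(embedding))
    methods::new("ClusterAssignment", labels = labels,
                 resolution = resolution,
                 nClusters = length(sizes))
}

#' Annotate clusters with a marker panel
#'
#' Computes dot-plot statistics for each (cluster, marker) pair: the mean
#' log-normalized expression and the fraction of cells with a non-zero
#' count. Each cluster is assigned the cell type whose markers reach the
#' highest average standardized (across clusters) mean expression,
#' direction-signed.
#'
#' @param x a [MesoCounts-class] object.
#' @param ca a [ClusterAssignment-class] over the same cells.
#' @param panel data.frame with columns `gene`, `cellType`, `direction`
#'   (`"up"` or `"down"`).
#' @return list with `assignment` (named character, cluster to cell
#'   type), `dotplot` (per cluster x marker statistics), and `missing`
#'   (panel genes absent from the matrix).
#' @export
annotateClusters <- function(x, ca, panel) {
    missing <- setdiff(panel$gene, rownames(x))
    panel <- panel[panel$gene %in% rownames(x), , drop = FALSE]
    if (nrow(panel) == 0) stop("no panel genes present in the matrix")
    e <- logNormCounts(x)[panel$gene, , drop = FALSE]
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))[
        panel$gene, , drop = FALSE]
    labels <- clusterLabels(ca)[colnames(x)]
    cl <- sort(unique(labels))
    dot <- do.call(rbind, lapply(cl, function(c) {
        i <- labels == c
        data.frame(cluster = c, gene = panel$gene,
                   cellType = panel$cellType,
                   meanExpr = rowMeans(e[, i, drop = FALSE]),
                   fracExpressing = rowMeans(cts[, i, drop = FALSE] > 0),
                   row.names = NULL)
    }))
    # standardize each marker's cluster means across clusters
    mm <- matrix(dot$meanExpr, nrow = length(cl), byrow = TRUE)
    zz <- scale(mm)
    zz[!is.finite(zz)] <- 0
    sgn <- ifelse(panel$direction == "down", -1, 1)
    types <- unique(panel$cellType)
    score <- vapply(types, function(ty) {
        j <- panel$cellType == ty
        rowMeans(sweep(zz[, j, drop = FALSE], 2, sgn[j], "*"))
    }, numeric(length(cl)))
    score <- matrix(score, nrow = length(cl),
                    dimnames = list(cl, types))
    assignment <- stats::setNames(
        types[apply(score, 1, which.max)], as.character(cl))
    list(assignment = assignment, dotplot = dot, missing = missing)
}
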