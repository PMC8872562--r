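# Pseudo-bulk construction and weighted coexpression (adjacency / TOM)
# networks.

#' Pool cells into pseudo-bulk samples
#'
#' Sums counts within each fine-resolution cell cluster, scales each
#' sample to reads per million (rows sum to 1e6) and log2(RPM + 1)
#' transforms. Each sample carries the mean pseudotime and the number of
#' its member cells. Empty clusters are excluded with a warning.
#'
#' @param x a [MesoCounts-class] object.
#' @param ca a fine-resolution [ClusterAssignment-class].
#' @param t a [Trajectory-class] covering the same cells.
#' @return A [PseudoBulk-class] object (one sample per cluster).
#' @export
makePseudobulk <- function(x, ca, t) {
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    labels <- clusterLabels(ca)[colnames(cts)]
    pt <- t@pseudotime[colnames(cts)]
    if (anyNA(labels) || anyNA(pt))
        stop("every cell needs a cluster label and a pseudotime")
    cl <- sort(unique(labels))
    agg <- t(vapply(cl, function(c)
        rowSums(cts[, labels == c, drop = FALSE]), numeric(nrow(cts))))
    rownames(agg) <- paste0("S", cl)
    tot <- rowSums(agg)
    empty <- tot == 0
    if (any(empty)) {
        warning(sum(empty), " empty pseudo-bulk sample(s) excluded")
        agg <- agg[!empty, , drop = FALSE]
        cl <- cl[!empty]
        tot <- tot[!empty]
    }
    rpm <- sweep(agg, 1, tot, "/") * 1e6
    methods::new("PseudoBulk",
        expr = log2(rpm + 1), rpm = rpm,
        samplePseudotime = stats::setNames(
            vapply(cl, function(c) mean(pt[labels == c]), numeric(1)),
            rownames(agg)),
        sampleSizes = stats::setNames(
            vapply(cl, function(c) sum(labels == c), integer(1)),
            rownames(agg)))
}

# Topological overlap matrix from an adjacency with unit diagonal.
# TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),
# k_i = sum_{u != i} a_iu; TOM_ii = 1.
tomFromAdjacency <- function(A) {
    diag(A) <- 1
    L <- A %*% A - 2 * A          # removes u = i and u = j terms (diag 1)
    k <- colSums(A) - 1
    minK <- outer(k, k, pmin)
    TOM <- (L + A) / (minK + 1 - A)
    diag(TOM) <- 1
    (TOM + t(TOM)) / 2            # symmetrize numerical noise
}

#' Build an unsigned weighted coexpression network
#'
#' Restricts to the top `topFrac` fraction of genes by expression
#' dispersion across pseudo-bulk samples, forms the unsigned adjacency
#' `|cor|^beta` (Pearson), the topological overlap matrix (TOM), module
#' labels from average-linkage hierarchical clustering of `1 - TOM`, and
#' an edge list of gene pairs whose TOM exceeds the `edgeQuantile`
#' quantile of off-diagonal TOM values.
#'
#' When `beta = NULL` the power is chosen as the smallest integer in
#' 1..20 whose degree distribution reaches a scale-free model fit
#' R-squared of at least 0.8, falling back to 6 with a warning.
#'
#' @param pb a [PseudoBulk-class] object (>= 4 samples).
#' @param topFrac fraction of genes retained by dispersion (default 0.75).
#' @param beta soft power; `NULL` for automatic selection.
#' @param edgeQuantile TOM quantile defining connections (default 0.95).
#' @param nModules number of module labels to cut the gene tree into.
#' @return A [CoexprNetwork-class] object.
#' @export
buildCoexpression <- function(pb, topFrac = 0.75, beta = NULL,
                              edgeQuantile = 0.95, nModules = 8) {
    if (nrow(pb@expr) < 4) stop("need at least 4 pseudo-bulk samples")
    e <- pb@expr
    mu <- colMeans(e)
    v <- apply(e, 2, stats::var)
    disp <- ifelse(mu > 0, v / mu, 0)
    nKeep <- round(topFrac * ncol(e))
    keep <- colnames(e)[order(-disp, colnames(e))][seq_len(nKeep)]
    e <- e[, keep, drop = FALSE]
    cc <- abs(stats::cor(e))
    cc[is.na(cc)] <- 0
    if (is.null(beta)) {
        beta <- pickSoftPower(cc)
        if (is.na(beta)) {
            warning("no power reached scale-free fit R^2 >= 0.8; ",
                    "falling back to beta = 6")
            beta <- 6
        }
    }
    A <- cc^beta
    diag(A) <- 1
    TOM <- tomFromAdjacency(A)
    off <- TOM[upper.tri(TOM)]
    thr <- stats::quantile(off, edgeQuantile, names = FALSE)
    idx <- which(upper.tri(TOM) & TOM >= thr, arr.ind = TRUE)
    edges <- data.frame(
        geneA = keep[idx[, 1]], geneB = keep[idx[, 2]],
        adjacency = A[idx], tom = TOM[idx])
    edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
    rownames(edges) <- NULL
    hc <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
    modules <- paste0("M", stats::cutree(hc, k = min(nModules, nKeep)))
    names(modules) <- keep
    methods::new("CoexprNetwork", beta = as.numeric(beta),
                 adjacency = A, tom = TOM, modules = modules,
                 edgeThreshold = thr, edges = edges)
}

# Scale-free topology criterion: regress log10 p(k) on log10 k over
# 10 degree bins; return smallest power with R^2 >= target.
pickSoftPower <- function(absCor, powers = 1:20, target = 0.8) {
    for (b in powers) {
        A <- absCor^b
        diag(A) <- 0
        k <- colSums(A)
        if (stats::sd(k) < 1e-12) next
        bins <- cut(k, breaks = 10)
        pk <- table(bins) / length(k)
        km <- tapply(k, bins, mean)
        ok <- !is.na(km) & pk > 0 & km > 0
        if (sum(ok) < 3) next
        fit <- stats::lm(log10(as.numeric(pk[ok])) ~ log10(km[ok]))
        r2 <- summary(fit)$r.squared
        if (r2 >= target && stats::coef(fit)[2] < 0) return(b)
    }
    NA_integer_
}
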