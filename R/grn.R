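# Linear-ODE regulatory-network inference with run averaging, consensus
# filtering, hub ranking and TF-family chi-squared enrichment.

#' Fit a linear-ODE regulatory network over pseudotime
#'
#' Latent linear-ODE inference: TF expression over pseudotime is
#' approximated as `x(t) ~ W exp(b t)` with a small latent dimension `z`.
#' Each run draws latent rates `b` uniformly from `bRange` and improves
#' them by iterative random replacement (one coordinate resampled per
#' iteration, kept when the least-squares reconstruction residual
#' drops; `W` is refit by ordinary least squares at every step). The run's
#' network is `A = W diag(b) pinv(W)`, so that `dx/dt ~ A x`, and the
#' reported `A` is the element-wise mean over `nRuns` random restarts,
#' which stabilizes edge weights considerably compared to single runs.
#'
#' @param expr TF x cells matrix of (log-scale) expression values.
#' @param pt per-cell pseudotime, required to lie in `[0, 1]`.
#' @param z latent dimension (default 4).
#' @param nRuns number of random restarts averaged (default 50).
#' @param iters random-replacement iterations per run (default 100).
#' @param bRange sampling range of latent rates (default `c(-10, 2)`).
#' @param seed RNG seed fixing the whole procedure.
#' @param center subtract each TF's mean before fitting (default TRUE;
#'   the latent model acts on deviations from baseline on the log scale).
#' @return An [OdeGrn-class] object; `A[i, j]` is the inferred effect of
#'   TF `j` on TF `i`.
#' @export
fitOdeGrn <- function(expr, pt, z = 4, nRuns = 50, iters = 100,
                      bRange = c(-10, 2), seed = 1, center = TRUE) {
    if (any(pt < 0 | pt > 1))
        stop("pseudotime must lie in [0, 1]")
    p <- nrow(expr)
    if (p < z + 1) stop("need at least z + 1 TFs")
    if (ncol(expr) != length(pt))
        stop("expr columns must match pseudotime length")
    X <- t(as.matrix(expr))                     # cells x TF
    if (center) X <- scale(X, center = TRUE, scale = FALSE)
    set.seed(seed)
    perRun <- vector("list", nRuns)
    bestOverall <- Inf
    Wbest <- NULL; bbest <- NULL
    dropped <- 0L
    for (r in seq_len(nRuns)) {
        b <- stats::runif(z, bRange[1], bRange[2])
        Z <- exp(outer(pt, b))
        fit <- stats::lm.fit(Z, X)
        rss <- sum(fit$residuals^2)
        for (it in seq_len(iters)) {
            j <- sample.int(z, 1)
            bNew <- b
            bNew[j] <- stats::runif(1, bRange[1], bRange[2])
            Znew <- Z
            Znew[, j] <- exp(pt * bNew[j])
            fitNew <- stats::lm.fit(Znew, X)
            rssNew <- sum(fitNew$residuals^2)
            if (rssNew < rss) {
                b <- bNew; Z <- Znew; fit <- fitNew; rss <- rssNew
            }
        }
        W <- t(fit$coefficients)                # TF x z
        A <- tryCatch(W %*% diag(b, z) %*% MASS::ginv(W),
                      error = function(e) NULL)
        if (is.null(A) || any(!is.finite(A))) {
            dropped <- dropped + 1L
            next
        }
        dimnames(A) <- list(rownames(expr), rownames(expr))
        perRun[[r]] <- A
        if (rss < bestOverall) {
            bestOverall <- rss; Wbest <- W; bbest <- b
        }
    }
    perRun <- perRun[!vapply(perRun, is.null, logical(1))]
    if (length(perRun) == 0) stop("all runs failed")
    if (dropped > 0)
        message(dropped, " run(s) discarded (singular loading matrix)")
    Abar <- Reduce(`+`, perRun) / length(perRun)
    methods::new("OdeGrn", A = Abar, W = Wbest, b = bbest,
                 nRuns = length(perRun), perRunA = perRun,
                 rss = bestOverall)
}

#' @describeIn fitOdeGrn averaged weight-matrix accessor.
#' @param x an `OdeGrn`.
#' @export
grnWeights <- function(x) x@A

#' Consensus of ODE and coexpression networks
#'
#' Keeps the directed edge (regulator j, target i) iff
#' `|A[i, j]| >= cutoff` and the unordered pair is a coexpression
#' connection. Cutoffs 0.1 (exploratory) and 0.5 (condensed) are the
#' conventional presets, applied to the absolute averaged weight so that
#' repressive edges are retained.
#'
#' @param ode an [OdeGrn-class] object.
#' @param co a [CoexprNetwork-class] object sharing gene ids.
#' @param cutoff absolute-weight cutoff.
#' @return A [ConsensusNetwork-class] object.
#' @export
consensusNetwork <- function(ode, co, cutoff = 0.1) {
    A <- ode@A
    genes <- rownames(A)
    coEdges <- networkEdges(co)
    shared <- intersect(genes, unique(c(coEdges$geneA, coEdges$geneB)))
    if (length(shared) == 0 && nrow(coEdges) > 0)
        warning("ODE and coexpression networks share no genes")
    coKey <- pairKey(coEdges$geneA, coEdges$geneB)
    tomOf <- stats::setNames(coEdges$tom, coKey)
    idx <- which(abs(A) >= cutoff & row(A) != col(A), arr.ind = TRUE)
    if (nrow(idx)) {
        reg <- genes[idx[, "col"]]; tgt <- genes[idx[, "row"]]
        key <- pairKey(reg, tgt)
        keep <- key %in% coKey
        edges <- data.frame(regulator = reg[keep], target = tgt[keep],
                            weight = A[idx][keep],
                            tom = unname(tomOf[key[keep]]))
        edges <- edges[order(edges$regulator, edges$target), ,
                       drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(regulator = character(), target = character(),
                            weight = numeric(), tom = numeric())
    }
    methods::new("ConsensusNetwork", edges = edges, cutoff = cutoff)
}

#' Rank hub nodes by degree
#'
#' Degree is counted over unique undirected partners; ties are broken by
#' the summed absolute edge weight, then by node id.
#'
#' @param net a [ConsensusNetwork-class] or [RegulatoryNetwork-class].
#' @param topK number of nodes to return (the full ranking if larger
#'   than the node count).
#' @return data.frame `node`, `degree`, `strength`, ranked.
#' @export
hubNodes <- function(net, topK = 10) {
    if (topK <= 0) stop("topK must be positive")
    edges <- networkEdges(net)
    if (nrow(edges) == 0) stop("network is empty")
    a <- edges[[1]]; b <- edges[[2]]
    w <- if ("weight" %in% names(edges)) abs(edges$weight) else
        rep(1, nrow(edges))
    key <- pairKey(a, b)
    first <- !duplicated(key)
    nodes <- unique(c(a, b))
    deg <- vapply(nodes, function(nd)
        sum((a[first] == nd) | (b[first] == nd)), numeric(1))
    str <- vapply(nodes, function(nd)
        sum(w[first][a[first] == nd | b[first] == nd]), numeric(1))
    out <- data.frame(node = nodes, degree = as.integer(deg),
                      strength = str)
    out <- out[order(-out$degree, -out$strength, out$node), ,
               drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, topK)
}

#' TF-family enrichment among highly expressed TFs
#'
#' For each family f, the expected number of highly expressed TFs in a
#' cell type is `|high| * n_f / N`, where `n_f` is the family size and
#' `N` the total TF count; enrichment is assessed per family by a
#' 2-category chi-squared test of observed (in-family, out-of-family)
#' counts against those expectations (df = 1). When a family's expected
#' count is zero an exact binomial test is used instead and the family
#' flagged. By construction the expected counts sum to `|high|`.
#'
#' @param highM character vector of TFs highly expressed in M cells.
#' @param highBS character vector of TFs highly expressed in BS cells.
#' @param familyMap named character: TF id to family for every known TF.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame per family with per-cell-type observed, expected,
#'   observed/expected ratio, chi-squared statistic, p-value and an
#'   `enriched` flag at `alpha`.
#' @export
tfFamilyEnrichment <- function(highM, highBS, familyMap, alpha = 0.01) {
    if (!all(c(highM, highBS) %in% names(familyMap)))
        stop("every listed TF must have a family annotation")
    N <- length(familyMap)
    fams <- sort(unique(familyMap))
    nF <- table(factor(familyMap, levels = fams))
    oneType <- function(high) {
        H <- length(high)
        obs <- table(factor(familyMap[high], levels = fams))
        expd <- H * as.numeric(nF) / N
        chi2 <- (as.numeric(obs) - expd)^2 / expd +
            ((H - as.numeric(obs)) - (H - expd))^2 / (H - expd)
        p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
        exactFlag <- expd == 0 | expd == H
        for (i in which(exactFlag)) {
            chi2[i] <- NA_real_
            p[i] <- stats::binom.test(obs[i], H,
                                      as.numeric(nF)[i] / N)$p.value
        }
        data.frame(observed = as.numeric(obs), expected = expd,
                   ratio = ifelse(expd > 0, as.numeric(obs) / expd, NA),
                   chi2 = chi2, p = p, exact = exactFlag)
    }
    m <- oneType(highM)
    b <- oneType(highBS)
    out <- data.frame(family = fams, nFamily = as.integer(nF),
                      nHighM = m$observed, expectedM = m$expected,
                      ratioM = m$ratio, chi2M = m$chi2, pM = m$p,
                      nHighBS = b$observed, expectedBS = b$expected,
                      ratioBS = b$ratio, chi2BS = b$chi2, pBS = b$p,
                      row.names = NULL)
    out$enrichedM <- !is.na(out$pM) & out$pM < alpha &
        out$nHighM > out$expectedM
    out$enrichedBS <- !is.na(out$pBS) & out$pBS < alpha &
        out$nHighBS > out$expectedBS
    out
}

#' Derive highly expressed TFs from a bulk expression table
#'
#' Helper defining "highly expressed" as the top quartile of the given
#' cell type's expression column, restricted to annotated TFs.
#'
#' @param bulk data.frame with a `gene` column and one expression column
#'   per cell type (RPM/FPKM scale).
#' @param cellType column name to use.
#' @param familyMap named character TF to family.
#' @param quantile top quantile (default 0.75).
#' @return character vector of TF ids.
#' @export
highExpressedTfs <- function(bulk, cellType, familyMap, quantile = 0.75) {
    tf <- bulk[bulk$gene %in% names(familyMap), , drop = FALSE]
    thr <- stats::quantile(tf[[cellType]], quantile, names = FALSE)
    tf$gene[tf[[cellType]] > thr]
}
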