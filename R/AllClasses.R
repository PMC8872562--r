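#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MesoCounts: a UMI count matrix with mitochondrial gene flags
#'
#' `MesoCounts` extends [SingleCellExperiment::SingleCellExperiment] and
#' represents a genes x cells UMI count matrix (assay `"counts"`) together
#' with a per-gene logical mitochondrial flag stored in `rowData(x)$mito`.
#' It is the entry object of the pipeline: quality control, normalization,
#' highly-variable-gene selection, embedding and clustering all operate
#' on it.
#'
#' @section Validity:
#' counts must be present, non-negative, with unique row (gene) and column
#' (cell) names; `rowData(x)$mito` must be a logical vector without `NA`.
#'
#' @seealso [MesoCounts()] for construction, [qcFilter()], [selectHvg()].
#' @aliases MesoCounts-class
#' @exportClass MesoCounts
setClass("MesoCounts", contains = "SingleCellExperiment")

setValidity("MesoCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (min(cts) < 0)
            msg <- c(msg, "counts must be non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell barcodes must be present and unique")
    mito <- SummarizedExperiment::rowData(object)$mito
    if (is.null(mito) || !is.logical(mito) || anyNA(mito) ||
        length(mito) != nrow(object))
        msg <- c(msg, "rowData(object)$mito must be a complete logical vector")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MesoCounts object
#'
#' @param counts genes x cells matrix (base or [Matrix::Matrix]) of
#'   non-negative UMI counts with row and column names.
#' @param mito logical per-gene mitochondrial flag, or a character vector of
#'   mitochondrial gene ids. Defaults to flagging gene ids starting with
#'   `"mito"` or `"MT-"` (case-insensitive).
#' @return A [MesoCounts-class] object.
#' @examples
#' cts <- matrix(rpois(20, 5), 4, 5,
#'               dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' MesoCounts(cts)
#' @export
MesoCounts <- function(counts, mito = NULL) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry gene ids (rownames) and cell ids (colnames)")
    if (is.null(mito))
        mito <- grepl("^(mito|mt-)", rownames(counts), ignore.case = TRUE)
    if (is.character(mito))
        mito <- rownames(counts) %in% mito
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(mito = mito))
    methods::new("MesoCounts", sce)
}

#' @describeIn MesoCounts per-gene mitochondrial flag accessor.
#' @param x a `MesoCounts` object.
#' @export
mitoMask <- function(x) SummarizedExperiment::rowData(x)$mito

#' Pseudotime trajectory over cells
#'
#' A per-cell pseudotime in \[0, 1\] together with the spanning-tree
#' backbone it was read off: centroid coordinates, tree edges, the root
#' cell, and a per-cell branch ("state") label. Pseudotime is min-max
#' normalized so the root cell sits at 0 and the farthest cell at 1.
#'
#' @slot pseudotime named numeric, one value in \[0, 1\] per cell.
#' @slot state named character, branch label per cell.
#' @slot rootCell character(1), barcode of the cell at pseudotime 0.
#' @slot treeEdges two-column integer matrix of centroid indices (MST).
#' @slot centroids numeric matrix of centroid coordinates in the reduced
#'   space the tree was learned in.
#' @slot embedding per-cell coordinates in the same reduced space.
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
    representation(pseudotime = "numeric", state = "character",
                   rootCell = "character", treeEdges = "matrix",
                   centroids = "matrix", embedding = "matrix"))

setValidity("Trajectory", function(object) {
    pt <- object@pseudotime
    msg <- NULL
    if (length(pt) == 0L || is.null(names(pt)))
        return("pseudotime must be a non-empty named numeric vector")
    if (any(pt < 0 | pt > 1))
        msg <- c(msg, "pseudotime must lie in [0, 1]")
    if (abs(min(pt)) > 1e-12 || abs(max(pt) - 1) > 1e-12)
        msg <- c(msg, "pseudotime must be min-max normalized to [0, 1]")
    if (!(object@rootCell %in% names(pt)) ||
        pt[object@rootCell] > 1e-12)
        msg <- c(msg, "rootCell must be a cell with pseudotime 0")
    if (length(object@state) != length(pt))
        msg <- c(msg, "state must have one label per cell")
    ne <- nrow(object@treeEdges)
    if (ne > 0 && ne != nrow(object@centroids) - 1L)
        msg <- c(msg, "tree must be a spanning tree (|E| = |V| - 1)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn Trajectory extract the named pseudotime vector.
#' @param object,x a `Trajectory`.
#' @export
pseudotime <- function(x) x@pseudotime

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory over", length(object@pseudotime), "cells\n")
    cat("  root cell:", object@rootCell, "\n")
    cat("  tree:", nrow(object@centroids), "centroids,",
        nrow(object@treeEdges), "edges,",
        length(unique(object@state)), "branch(es)\n")
})

#' Ground-truth regulatory network for simulation
#'
#' The signed TF x TF weight matrix that drives the latent linear ODE of
#' the cell simulator, plus its edge list. The diagonal is strictly
#' negative (first-order self-degradation), which keeps the latent
#' dynamics bounded on the unit time interval.
#'
#' @slot tfIds character, regulator/TF gene ids (rows and columns of A).
#' @slot targetIds character, non-TF target gene ids driven by templates.
#' @slot A signed TF x TF weight matrix; `A[i, j]` is the effect of TF j
#'   on TF i.
#' @slot edges data.frame with columns `regulator`, `target`, `sign`.
#' @slot density fraction of non-zero off-diagonal entries requested.
#' @aliases GrnTruth-class
#' @exportClass GrnTruth
setClass("GrnTruth",
    representation(tfIds = "character", targetIds = "character",
                   A = "matrix", edges = "data.frame", density = "numeric"))

setValidity("GrnTruth", function(object) {
    msg <- NULL
    A <- object@A
    if (nrow(A) != ncol(A) || nrow(A) != length(object@tfIds))
        msg <- c(msg, "A must be square TF x TF")
    if (any(!is.finite(A)))
        msg <- c(msg, "weights must be finite")
    if (any(diag(A) >= 0))
        msg <- c(msg, "diagonal of A must be strictly negative")
    offdiag <- A; diag(offdiag) <- 0
    if (sum(offdiag != 0) != nrow(object@edges))
        msg <- c(msg, "edge list must enumerate the off-diagonal non-zeros")
    ok <- c(object@edges$regulator, object@edges$target) %in%
        c(object@tfIds, object@targetIds)
    if (!all(ok))
        msg <- c(msg, "every edge endpoint must be a known gene id")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "GrnTruth", function(object) {
    cat("GrnTruth:", length(object@tfIds), "TFs,",
        length(object@targetIds), "targets,",
        nrow(object@edges), "true edges",
        sprintf("(requested density %.3g)\n", object@density))
})

#' Ground truth of a synthetic data set
#'
#' Book-keeping of everything the generator planted, so downstream stages
#' can be scored exactly: the latent per-cell time, cell types, planted
#' low-quality cells with reasons, gene dynamic templates, planted motif
#' instances, and planted loop- and peak-supported regulatory pairs.
#'
#' @slot trueTime named numeric in \[0, 1\], the latent time per cell.
#' @slot cellType named character (`"M"`, `"BS"`, ...).
#' @slot lowQuality data.frame with columns `cell`, `reason`
#'   (`"reads"` or `"mito"`).
#' @slot dynamicLabels named character per gene:
#'   `"increasing"`, `"decreasing"`, `"transient"`, `"flat"` or `"ode"`.
#' @slot motifPositions data.frame `seq`, `offset` (1-based within the
#'   promoter sequence), `strand`.
#' @slot loopPairs data.frame `geneA`, `geneB`, `kind` (`"PPI"`/`"PDI"`).
#' @slot chipPairs data.frame `tf`, `target` for planted promoter
#'   ChIP peaks.
#' @aliases SynTruth-class
#' @exportClass SynTruth
setClass("SynTruth",
    representation(trueTime = "numeric", cellType = "character",
                   lowQuality = "data.frame", dynamicLabels = "character",
                   motifPositions = "data.frame", loopPairs = "data.frame",
                   chipPairs = "data.frame"))

setValidity("SynTruth", function(object) {
    msg <- NULL
    tt <- object@trueTime
    if (length(tt) && (any(tt < 0 | tt > 1)))
        msg <- c(msg, "trueTime must lie in [0, 1]")
    if (length(tt) && length(object@cellType) != length(tt))
        msg <- c(msg, "cellType must align with trueTime")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SynTruth", function(object) {
    cat("SynTruth:", length(object@trueTime), "cells,",
        nrow(object@lowQuality), "planted low-quality,",
        nrow(object@motifPositions), "planted motifs,",
        nrow(object@loopPairs), "loop-supported pairs\n")
})

#' Position weight matrix
#'
#' A width x 4 matrix of base probabilities (columns A, C, G, T) with a
#' background distribution, used for log-odds scanning of promoter
#' sequences. Fully degenerate positions (e.g. the `nn` of the HSF motif
#' consensus AGAAnnTTCT) carry uniform rows.
#'
#' @slot mat width x 4 probability matrix, rows summing to 1.
#' @slot background length-4 background probabilities.
#' @slot name motif identifier.
#' @aliases Pwm-class
#' @exportClass Pwm
setClass("Pwm",
    representation(mat = "matrix", background = "numeric", name = "character"))

setValidity("Pwm", function(object) {
    msg <- NULL
    if (ncol(object@mat) != 4L ||
        !identical(colnames(object@mat), c("A", "C", "G", "T")))
        msg <- c(msg, "mat must have columns A, C, G, T")
    if (any(abs(rowSums(object@mat) - 1) > 1e-6))
        msg <- c(msg, "PWM rows must sum to 1 (tolerance 1e-6)")
    if (length(object@background) != 4L ||
        abs(sum(object@background) - 1) > 1e-6)
        msg <- c(msg, "background must be 4 probabilities summing to 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a Pwm
#'
#' @param mat width x 4 probability matrix (columns A, C, G, T).
#' @param background length-4 background; default uniform.
#' @param name motif name.
#' @return A [Pwm-class] object.
#' @export
Pwm <- function(mat, background = rep(0.25, 4), name = "motif") {
    colnames(mat) <- c("A", "C", "G", "T")
    methods::new("Pwm", mat = mat, background = background, name = name)
}

setMethod("show", "Pwm", function(object) {
    cat("Pwm", object@name, "of width", nrow(object@mat),
        "- consensus", pwmConsensus(object), "\n")
})

#' Fitted linear-ODE regulatory network
#'
#' The result of latent linear-ODE network inference: expression of p TFs
#' over pseudotime is approximated by `W %*% exp(b t)` with a small latent
#' dimension z; each run yields a signed TF x TF matrix
#' `A = W diag(b) pinv(W)` and the reported `A` is the element-wise mean
#' over random restarts.
#'
#' @slot A averaged signed TF x TF weight matrix (`A[i, j]`: regulation of
#'   TF i by TF j).
#' @slot W TF x z loading matrix of the best run.
#' @slot b latent rates of the best run.
#' @slot nRuns number of successful runs averaged.
#' @slot perRunA list of per-run A matrices (variance diagnostics).
#' @slot rss residual sum of squares of the best run.
#' @aliases OdeGrn-class
#' @exportClass OdeGrn
setClass("OdeGrn",
    representation(A = "matrix", W = "matrix", b = "numeric",
                   nRuns = "integer", perRunA = "list", rss = "numeric"))

setValidity("OdeGrn", function(object) {
    msg <- NULL
    if (nrow(object@A) != ncol(object@A))
        msg <- c(msg, "A must be square")
    if (length(object@perRunA) &&
        length(object@perRunA) != object@nRuns)
        msg <- c(msg, "perRunA must hold one matrix per successful run")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "OdeGrn", function(object) {
    cat("OdeGrn over", nrow(object@A), "TFs, z =", length(object@b),
        ", averaged over", object@nRuns, "runs\n")
})

#' Weighted coexpression network on pseudo-bulk samples
#'
#' Unsigned weighted network: adjacency `|cor|^beta` on the top-dispersed
#' genes of a pseudo-bulk expression matrix, topological overlap matrix
#' (TOM), module labels from hierarchical clustering of the TOM
#' dissimilarity, and the edge set above a TOM quantile threshold.
#'
#' @slot beta soft-thresholding power.
#' @slot adjacency symmetric gene x gene matrix in \[0, 1\], unit diagonal.
#' @slot tom symmetric TOM in \[0, 1\], unit diagonal.
#' @slot modules named module label per gene.
#' @slot edgeThreshold TOM value above which pairs count as connections.
#' @slot edges data.frame `geneA`, `geneB`, `adjacency`, `tom`.
#' @aliases CoexprNetwork-class
#' @exportClass CoexprNetwork
setClass("CoexprNetwork",
    representation(beta = "numeric", adjacency = "matrix", tom = "matrix",
                   modules = "character", edgeThreshold = "numeric",
                   edges = "data.frame"))

setValidity("CoexprNetwork", function(object) {
    msg <- NULL
    A <- object@adjacency; TOM <- object@tom
    if (!isSymmetric(unname(A)) || !isSymmetric(unname(TOM)))
        msg <- c(msg, "adjacency and TOM must be symmetric")
    if (any(A < 0 | A > 1) || any(TOM < -1e-12 | TOM > 1 + 1e-12))
        msg <- c(msg, "adjacency and TOM entries must lie in [0, 1]")
    if (any(abs(diag(A) - 1) > 1e-12) || any(abs(diag(TOM) - 1) > 1e-12))
        msg <- c(msg, "adjacency and TOM must have unit diagonal")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CoexprNetwork", function(object) {
    cat("CoexprNetwork:", nrow(object@adjacency), "genes, beta =",
        object@beta, ",", nrow(object@edges), "edges (TOM >",
        signif(object@edgeThreshold, 3), "),",
        length(unique(object@modules)), "modules\n")
})

#' Consensus of ODE and coexpression networks
#'
#' Directed edges whose averaged ODE weight passes `|A| >= cutoff` and
#' whose unordered gene pair is also a coexpression connection. Each edge
#' carries both parents' evidence.
#'
#' @slot edges data.frame `regulator`, `target`, `weight` (signed ODE
#'   weight), `tom` (coexpression support).
#' @slot cutoff absolute-weight cutoff applied to the ODE matrix.
#' @aliases ConsensusNetwork-class
#' @exportClass ConsensusNetwork
setClass("ConsensusNetwork",
    representation(edges = "data.frame", cutoff = "numeric"))

setMethod("show", "ConsensusNetwork", function(object) {
    cat("ConsensusNetwork:", nrow(object@edges), "edges at |weight| >=",
        object@cutoff, "\n")
})

#' Typed multi-omic regulatory network
#'
#' Edges of four types with recorded provenance: `predicted` (consensus
#' network), `chip_direct` (TF ChIP peak within the target promoter
#' window), `PPI` (promoter-promoter contact through a chain of
#' anchor-overlapping chromatin loops) and `PDI` (TF peak on a distal
#' accessible region that loops to the target promoter).
#'
#' @slot edges data.frame `from`, `to`, `type`, `provenance` (semicolon-
#'   separated `key=value` records naming the peaks/loops/consensus edge
#'   that justify the edge).
#' @aliases RegulatoryNetwork-class
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork", representation(edges = "data.frame"))

setMethod("show", "RegulatoryNetwork", function(object) {
    tab <- table(object@edges$type)
    cat("RegulatoryNetwork:", nrow(object@edges), "edges (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

#' @describeIn RegulatoryNetwork edge table accessor (also works for
#'   consensus and coexpression networks).
#' @param x a network object.
#' @export
networkEdges <- function(x) x@edges

#' Pseudo-bulk expression set
#'
#' Cluster-pooled expression: per fine cluster, counts are summed, scaled
#' to reads-per-million and log2(RPM + 1) transformed; each sample carries
#' the mean pseudotime of its member cells.
#'
#' @slot expr samples x genes matrix of log2(RPM + 1).
#' @slot rpm samples x genes matrix of RPM (rows sum to 1e6).
#' @slot samplePseudotime named mean pseudotime per sample.
#' @slot sampleSizes named cell count per sample.
#' @aliases PseudoBulk-class
#' @exportClass PseudoBulk
setClass("PseudoBulk",
    representation(expr = "matrix", rpm = "matrix",
                   samplePseudotime = "numeric", sampleSizes = "integer"))

setValidity("PseudoBulk", function(object) {
    msg <- NULL
    if (!all(abs(rowSums(object@rpm) - 1e6) < 1e-3))
        msg <- c(msg, "RPM rows must sum to 1e6")
    if (length(object@samplePseudotime) != nrow(object@expr))
        msg <- c(msg, "one pseudotime per sample required")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "PseudoBulk", function(object) {
    cat("PseudoBulk:", nrow(object@expr), "samples x", ncol(object@expr),
        "genes; cells per sample:",
        paste(range(object@sampleSizes), collapse = "-"), "\n")
})

#' TSS-centered metagene profile
#'
#' Mean normalized coverage in fixed-width bins across the window
#' \[TSS - flank, TSS + flank) for each gene group, with minus-strand
#' genes reversed so bins always run 5' to 3'.
#'
#' @slot profile groups x bins matrix of mean normalized coverage.
#' @slot flank half-window in bp.
#' @slot bin bin width in bp.
#' @slot nGenes named number of genes contributing per group.
#' @aliases MetaProfile-class
#' @exportClass MetaProfile
setClass("MetaProfile",
    representation(profile = "matrix", flank = "numeric", bin = "numeric",
                   nGenes = "integer"))

setValidity("MetaProfile", function(object) {
    if (ncol(object@profile) != 2 * object@flank / object@bin)
        "bin count must equal 2*flank/bin" else TRUE
})

setMethod("show", "MetaProfile", function(object) {
    cat("MetaProfile:", nrow(object@profile), "group(s) x",
        ncol(object@profile), "bins (flank", object@flank, "bp, bin",
        object@bin, "bp)\n")
})

#' Aggregated nuclease footprint profile
#'
#' Per-base mean coverage around aligned motif occurrences (minus-strand
#' sites reversed), revealing the protection dip of a bound factor.
#'
#' @slot profile numeric, length 2*w + motif width.
#' @slot nSites number of sites averaged.
#' @slot motifWidth motif width in bp.
#' @slot w flank in bp on each side of the motif span.
#' @aliases FootprintProfile-class
#' @exportClass FootprintProfile
setClass("FootprintProfile",
    representation(profile = "numeric", nSites = "integer",
                   motifWidth = "integer", w = "integer"))

setValidity("FootprintProfile", function(object) {
    msg <- NULL
    if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
    if (length(object@profile) != 2L * object@w + object@motifWidth)
        msg <- c(msg, "profile length must be 2*w + motif width")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "FootprintProfile", function(object) {
    cat("FootprintProfile over", object@nSites, "sites; window",
        length(object@profile), "bp; minimum at offset",
        which.min(object@profile), "\n")
})
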