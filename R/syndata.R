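# Synthetic-data generators: every input the pipeline consumes, with
# recorded ground truth (latent cell times, true network, planted
# low-quality cells, motifs, peaks and loops).

#' Simulate a ground-truth TF regulatory network
#'
#' Draws a signed TF x TF weight matrix whose diagonal is strictly
#' negative (first-order self-degradation) and whose off-diagonal entries
#' are non-zero independently with probability `density`. Edge magnitudes
#' are uniform on `[0.5, 1.5] * weightScale` with random sign, so planted
#' edges are neither vanishing nor dominating. Self-degradation rates are
#' drawn from `[0.2, 0.5] * weightScale`, i.e. slower than the regulatory
#' couplings, so that the observable dynamics on the unit time interval
#' are dominated by regulation rather than by uniform decay - the regime
#' in which trajectory-based network inference is informative.
#'
#' @param nTf number of transcription factors (>= 2).
#' @param density probability of an off-diagonal edge, in `[0, 1)`.
#' @param weightScale magnitude scale of weights.
#' @param seed RNG seed; fixed seed gives an identical network.
#' @return A [GrnTruth-class] object.
#' @examples
#' simulateGrn(5, density = 0.2, seed = 1)
#' @export
simulateGrn <- function(nTf, density = 0.1, weightScale = 1, seed = 1) {
    if (nTf < 2) stop("nTf must be >= 2")
    if (density < 0 || density >= 1)
        stop("density must lie in [0, 1)")
    set.seed(seed)
    ids <- sprintf("TF%02d", seq_len(nTf))
    A <- matrix(0, nTf, nTf, dimnames = list(ids, ids))
    off <- which(row(A) != col(A))
    hit <- off[stats::runif(length(off)) < density]
    A[hit] <- sample(c(-1, 1), length(hit), replace = TRUE) *
        stats::runif(length(hit), 0.5, 1.5) * weightScale
    diag(A) <- -stats::runif(nTf, 0.2, 0.5) * weightScale
    idx <- which(A != 0 & row(A) != col(A), arr.ind = TRUE)
    edges <- data.frame(
        regulator = ids[idx[, "col"]],
        target = ids[idx[, "row"]],
        sign = sign(A[idx]))
    edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
    methods::new("GrnTruth", tfIds = ids, targetIds = character(),
                 A = A, edges = edges, density = density)
}

# Dynamic templates on latent time t in [0,1], standardized to [-1, 1].
templateProfile <- function(label, t) {
    switch(label,
        increasing = 2 * t - 1,
        decreasing = 1 - 2 * t,
        transient  = 2 * exp(-(t - 0.5)^2 / (2 * 0.15^2)) - 1,
        flat       = rep(0, length(t)),
        stop("unknown template ", label))
}

#' Simulate a single-cell UMI count matrix with ground truth
#'
#' Each cell carries a latent developmental time drawn uniformly on
#' `[0, 1]`. TF expression follows the latent linear ODE of `grn`
#' (`dz/dt = A z`, solved in closed form); target genes follow monotone,
#' transient or flat templates; a minority bundle-sheath-like population
#' receives additive marker offsets on a dedicated marker panel. Counts
#' are sampled per cell by a Dirichlet-multinomial: the Dirichlet layer
#' supplies negative-binomial-like per-gene overdispersion while the
#' multinomial layer makes each cell's total exactly its sampled library
#' size. A mitochondrial gene block receives a fixed read fraction, and
#' `nLowq` planted cells violate the standard QC thresholds (library size
#' below 10,000 reads, or mitochondrial ratio above 0.2).
#'
#' @param grn a [GrnTruth-class] network driving the TF dynamics.
#' @param nCells number of cells.
#' @param nTargets number of template-driven target genes.
#' @param depthMean mean library size (reads per cell); non-planted cells
#'   are kept above 60% of this value so only planted cells can fail the
#'   read-count QC threshold.
#' @param mitoFrac expected mitochondrial read fraction of normal cells.
#' @param nLowq number of planted low-quality cells (alternating reasons:
#'   low reads, high mitochondrial fraction).
#' @param nbDispersion overdispersion of the Dirichlet layer (larger =
#'   noisier; 0 would be multinomial).
#' @param seed RNG seed.
#' @param mode `"ode"` (TF dynamics from the linear ODE; the inference
#'   model family) or `"logistic"` (sigmoid templates; robustness mode).
#' @param nFlat number of flat non-dynamic genes.
#' @param nMito number of mitochondrial genes.
#' @param bsFrac fraction of bundle-sheath-like cells.
#' @param ampTargets log-scale amplitude of target templates
#'   (default log(2.5): >2-fold swing across the trajectory).
#' @return list with `counts` ([MesoCounts-class]), `truth`
#'   ([SynTruth-class]), `latent` (TF x cells latent states),
#'   `depth` (named sampled library size per cell; column sums of the
#'   matrix equal it exactly), `markerPanel` (data.frame
#'   gene/cellType/direction).
#' @export
simulateCells <- function(grn, nCells = 500, nTargets = 150,
                          depthMean = 20000, mitoFrac = 0.05, nLowq = 0,
                          nbDispersion = 0.5, seed = 1,
                          mode = c("ode", "logistic"),
                          nFlat = 20, nMito = 10, bsFrac = 0.1,
                          ampTargets = log(2.5)) {
    mode <- match.arg(mode)
    if (nLowq > nCells) stop("nLowq cannot exceed nCells")
    if (any(diag(grn@A) >= 0)) stop("grn must have negative diagonal")
    set.seed(seed)

    nTf <- length(grn@tfIds)
    trueTime <- stats::runif(nCells)
    cellIds <- sprintf("cell%04d", seq_len(nCells))
    names(trueTime) <- cellIds
    cellType <- ifelse(stats::runif(nCells) < bsFrac, "BS", "M")
    names(cellType) <- cellIds

    # latent TF states
    if (mode == "ode") {
        z0 <- stats::runif(nTf, 0.5, 1.5)
        latent <- odeTrajectory(grn@A, z0, trueTime)
    } else {
        mid <- stats::runif(nTf, 0.2, 0.8)
        latent <- t(vapply(mid, function(m)
            1 / (1 + exp(-(trueTime - m) / 0.15)), numeric(nCells)))
        rownames(latent) <- grn@tfIds
    }
    colnames(latent) <- cellIds
    zs <- latent - rowMeans(latent)
    sds <- apply(latent, 1, stats::sd)
    zs <- zs / ifelse(sds < 1e-9, 1, sds)

    tmplPool <- c("increasing", "decreasing", "transient")
    targetIds <- sprintf("tgt%03d", seq_len(nTargets))
    targetLbl <- tmplPool[(seq_len(nTargets) - 1L) %% 3L + 1L]
    flatIds <- sprintf("flat%02d", seq_len(nFlat))
    mIds <- sprintf("markM%02d", 1:8)
    bIds <- sprintf("markBS%02d", 1:8)
    mitoIds <- sprintf("mito%02d", seq_len(nMito))
    geneIds <- c(grn@tfIds, targetIds, flatIds, mIds, bIds, mitoIds)

    nNuc <- length(geneIds) - nMito
    base <- stats::runif(nNuc, log(5), log(50))
    logRel <- matrix(base, nNuc, nCells,
                     dimnames = list(geneIds[seq_len(nNuc)], cellIds))
    logRel[grn@tfIds, ] <- logRel[grn@tfIds, ] + zs
    for (k in seq_len(nTargets))
        logRel[targetIds[k], ] <- logRel[targetIds[k], ] +
            ampTargets * templateProfile(targetLbl[k], trueTime)
    isBS <- cellType == "BS"
    logRel[mIds, !isBS] <- logRel[mIds, !isBS] + log(4)
    logRel[bIds, isBS] <- logRel[bIds, isBS] + log(6)
    rel <- exp(logRel)

    # planted failures
    lowQuality <- data.frame(cell = character(), reason = character())
    mitoTarget <- rep(mitoFrac, nCells)
    depth <- round(exp(stats::rnorm(nCells, log(depthMean), 0.25)))
    floorDepth <- ceiling(0.6 * depthMean)
    depth[depth < floorDepth] <- floorDepth
    if (nLowq > 0) {
        planted <- sample(nCells, nLowq)
        reason <- rep(c("reads", "mito"), length.out = nLowq)
        depth[planted[reason == "reads"]] <-
            round(stats::runif(sum(reason == "reads"), 3000, 8000))
        mitoTarget[planted[reason == "mito"]] <- 0.35
        lowQuality <- data.frame(cell = cellIds[planted], reason = reason)
        lowQuality <- lowQuality[order(lowQuality$cell), ]
        rownames(lowQuality) <- NULL
    }

    mitoW <- stats::runif(nMito, 0.5, 1.5)
    conc <- length(geneIds) / nbDispersion
    counts <- matrix(0L, length(geneIds), nCells,
                     dimnames = list(geneIds, cellIds))
    for (c in seq_len(nCells)) {
        p <- c(rel[, c] / sum(rel[, c]) * (1 - mitoTarget[c]),
               mitoW / sum(mitoW) * mitoTarget[c])
        a <- stats::rgamma(length(p), shape = p * conc)
        a[a <= 0] <- 1e-12
        counts[, c] <- stats::rmultinom(1, depth[c], a / sum(a))
    }

    labels <- c(rep("ode", nTf), targetLbl, rep("flat", nFlat),
                rep("flat", 16), rep("flat", nMito))
    names(labels) <- geneIds
    truth <- methods::new("SynTruth",
        trueTime = trueTime, cellType = cellType,
        lowQuality = lowQuality, dynamicLabels = labels,
        motifPositions = data.frame(), loopPairs = data.frame(),
        chipPairs = data.frame())
    panel <- data.frame(
        gene = c(mIds, bIds),
        cellType = rep(c("M", "BS"), each = 8),
        direction = "up")
    list(counts = MesoCounts(counts, mito = mitoIds), truth = truth,
         latent = latent, depth = stats::setNames(depth, cellIds),
         markerPanel = panel)
}

#' HSF-consensus position weight matrix
#'
#' PWM for the palindromic heat-shock-factor binding consensus AGAAnnTTCT:
#' informative positions put probability `1 - 3*eps` on the consensus base;
#' the two central degenerate positions are uniform.
#'
#' @param eps per-off-base probability at informative positions.
#' @return A [Pwm-class] object named `"HSF"`.
#' @export
hsfPwm <- function(eps = 0.03) {
    cons <- strsplit("AGAAnnTTCT", "")[[1]]
    mat <- t(vapply(cons, function(b) {
        if (b == "n") rep(0.25, 4)
        else {
            p <- rep(eps, 4)
            p[match(b, c("A", "C", "G", "T"))] <- 1 - 3 * eps
            p
        }
    }, numeric(4)))
    rownames(mat) <- NULL
    Pwm(mat, name = "HSF")
}

#' Random decoy PWM
#'
#' A sharply informative PWM over a random base sequence; used as a decoy
#' in motif-enrichment benchmarks.
#'
#' @param width motif width.
#' @param seed RNG seed.
#' @param name motif name.
#' @return A [Pwm-class] object.
#' @export
randomPwm <- function(width = 10, seed = 1, name = paste0("decoy", seed)) {
    set.seed(seed)
    cons <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    mat <- t(vapply(cons, function(b) {
        p <- rep(0.03, 4); p[match(b, c("A", "C", "G", "T"))] <- 0.91; p
    }, numeric(4)))
    rownames(mat) <- NULL
    Pwm(mat, name = name)
}

# Concrete motif instance of a PWM: consensus base at informative
# positions, sampled base at degenerate (near-uniform) positions, so a
# planted instance always scores at the scanning threshold.
sampleMotifInstance <- function(pwm) {
    paste(apply(pwm@mat, 1, function(p) {
        if (max(p) < 0.5) sample(c("A", "C", "G", "T"), 1, prob = p)
        else c("A", "C", "G", "T")[which.max(p)]
    }), collapse = "")
}

#' Simulate a toy genome with planted regulatory features
#'
#' Places `nGenes` non-overlapping genes with alternating strand on a
#' single toy chromosome; builds a random chromosome sequence;
#' plants PWM instances into a recorded subset of promoters; creates
#' MNase-hypersensitivity peaks over promoters; writes a coverage track
#' that is elevated within peaks and depleted by `footprintDepth` across
#' each planted motif (the footprint); and plants TF ChIP peaks, distal
#' accessible regions (dACRs) and chromatin loops that realize a known
#' set of promoter-promoter (PPI, including one two-loop chain when
#' `nLoops >= 2`) and promoter-distal (PDI) regulatory pairs. Distinct
#' genes are used for every planted structure so the recorded truth is
#' exhaustive: no unplanted pair satisfies any edge rule.
#'
#' @param nGenes number of genes.
#' @param chromLen chromosome length in bp.
#' @param pwm the true motif ([Pwm-class]); default [hsfPwm()].
#' @param motifFrac fraction of promoters receiving a planted motif.
#' @param footprintDepth fractional coverage depletion over planted
#'   motifs, in (0, 1).
#' @param nLoops number of promoter-promoter loops (>= 2 builds one
#'   two-loop chain plus single loops).
#' @param nChip number of planted direct TF-promoter ChIP pairs.
#' @param nPdi number of planted TF-dACR-loop-promoter structures.
#' @param promWidth promoter sequence length (bp upstream of the TSS).
#' @param seed RNG seed.
#' @return list with `annotation` (GRanges with `gene_id`), `mhs`,
#'   `dacrs` (GRanges), `tfPeaks` (named list of GRanges per TF),
#'   `loops` ([S4Vectors::Pairs] of anchors), `promoters`
#'   (named [Biostrings::DNAStringSet]), `coverage` (GRanges with
#'   `score`, bedGraph-ready), `chromLen`, and `truth`
#'   ([SynTruth-class] with `motifPositions`, `loopPairs`, `chipPairs`).
#' @export
simulateGenomeTracks <- function(nGenes = 30, chromLen = 200000,
                                 pwm = hsfPwm(), motifFrac = 0.4,
                                 footprintDepth = 0.5, nLoops = 4,
                                 nChip = 4, nPdi = 3, promWidth = 500,
                                 seed = 1) {
    w <- nrow(pwm@mat)
    if (w >= promWidth) stop("motif width must be below promoter length")
    spacing <- chromLen %/% (nGenes + 1L)
    if (spacing < 2L * (promWidth + 1500L))
        stop("chromLen too small to place ", nGenes, " genes")
    nStruct <- (if (nLoops >= 2) 3L + 2L * (nLoops - 2L) else 2L * nLoops) +
        2L * nChip + 2L * nPdi
    if (nStruct > nGenes)
        stop("not enough genes for the requested loop/peak structures")
    set.seed(seed)

    geneIds <- sprintf("gene%03d", seq_len(nGenes))
    tss <- spacing * seq_len(nGenes)
    strand <- rep(c("+", "-"), length.out = nGenes)
    gstart <- ifelse(strand == "+", tss, tss - 999L)
    gend <- ifelse(strand == "+", tss + 999L, tss)
    ann <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(gstart, gend), strand = strand,
        gene_id = geneIds, seqlengths = c(chr1 = chromLen))

    genome <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)

    # plant motifs (coordinates recorded in promoter-sequence space)
    nPick <- round(motifFrac * nGenes)
    withMotif <- sort(sample(nGenes, nPick))
    mp <- data.frame(seq = character(), offset = integer(),
                     strand = character(), genomicStart = integer())
    for (i in withMotif) {
        o <- sample(seq(20L, promWidth - w - 20L), 1)
        ms <- if (stats::runif(1) < 0.7) "+" else "-"
        inst <- sampleMotifInstance(pwm)
        instP <- if (ms == "+") inst else revcompStr(inst)  # promoter-strand
        if (strand[i] == "+") {
            gs <- tss[i] - promWidth + o - 1L   # promoter = [tss-pw, tss-1]
            genome[gs:(gs + w - 1L)] <- strsplit(instP, "")[[1]]
        } else {
            ge <- tss[i] + promWidth - (o - 1L) # promoter = rc([tss+1, tss+pw])
            gs <- ge - w + 1L
            genome[gs:(gs + w - 1L)] <- strsplit(revcompStr(instP), "")[[1]]
        }
        mp <- rbind(mp, data.frame(seq = geneIds[i], offset = o,
                                   strand = ms, genomicStart = gs))
    }

    chrom <- Biostrings::DNAString(paste(genome, collapse = ""))
    promSeq <- vapply(seq_len(nGenes), function(i) {
        if (strand[i] == "+")
            as.character(chrom[(tss[i] - promWidth):(tss[i] - 1L)])
        else
            as.character(Biostrings::reverseComplement(
                chrom[(tss[i] + 1L):(tss[i] + promWidth)]))
    }, character(1))
    promoters <- Biostrings::DNAStringSet(promSeq)
    names(promoters) <- geneIds

    # MNase-hypersensitive peaks: promoter plus 100 bp downstream of TSS
    mhsStart <- ifelse(strand == "+", tss - promWidth, tss - 99L)
    mhsEnd <- ifelse(strand == "+", tss + 99L, tss + promWidth)
    mhs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mhsStart, mhsEnd),
        name = paste0("mhs_", geneIds), seqlengths = c(chr1 = chromLen))

    # coverage: baseline 1, peaks 10, footprint depletion at motifs
    cov <- S4Vectors::Rle(1, chromLen)
    for (k in seq_along(mhs))
        cov[mhsStart[k]:mhsEnd[k]] <- 10
    if (nrow(mp) > 0 && footprintDepth > 0)
        for (k in seq_len(nrow(mp))) {
            span <- mp$genomicStart[k]:(mp$genomicStart[k] + w - 1L)
            cov[span] <- as.numeric(cov[span]) * (1 - footprintDepth)
        }
    covGr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = cumsum(c(1, S4Vectors::runLength(cov)))[
                             seq_along(S4Vectors::runLength(cov))],
                         width = S4Vectors::runLength(cov)),
        score = S4Vectors::runValue(cov), seqlengths = c(chr1 = chromLen))

    # structural roles on disjoint genes
    pool <- seq_len(nGenes)
    takeGenes <- function(n) {
        g <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; g
    }
    loopA <- integer(); loopB <- integer()
    loopPairs <- data.frame(geneA = character(), geneB = character(),
                            kind = character())
    anchorAt <- function(i, lo, hi)
        c(tss[i] + lo, tss[i] + hi)  # 1-based closed interval
    anchors1 <- matrix(numeric(0), ncol = 2)
    anchors2 <- matrix(numeric(0), ncol = 2)
    addLoop <- function(a1, a2) {
        anchors1 <<- rbind(anchors1, a1); anchors2 <<- rbind(anchors2, a2)
    }
    if (nLoops >= 2) {
        g <- takeGenes(3L)   # chain: A-B, B-C => pairs AB, BC, AC
        addLoop(anchorAt(g[1], -400, 399), anchorAt(g[2], -400, 199))
        addLoop(anchorAt(g[2], -200, 399), anchorAt(g[3], -400, 399))
        ids <- geneIds[g]
        loopPairs <- rbind(loopPairs, data.frame(
            geneA = c(ids[1], ids[2], ids[1]),
            geneB = c(ids[2], ids[3], ids[3]), kind = "PPI"))
        nSingle <- nLoops - 2L
    } else nSingle <- nLoops
    for (s in seq_len(nSingle)) {
        g <- takeGenes(2L)
        addLoop(anchorAt(g[1], -400, 399), anchorAt(g[2], -400, 399))
        loopPairs <- rbind(loopPairs, data.frame(
            geneA = geneIds[g[1]], geneB = geneIds[g[2]], kind = "PPI"))
    }

    tfPeaks <- list()
    chipPairs <- data.frame(tf = character(), target = character())
    for (s in seq_len(nChip)) {
        g <- takeGenes(2L)
        tf <- geneIds[g[1]]; tgt <- geneIds[g[2]]
        pk <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(tss[g[2]] - 200L, tss[g[2]] + 199L),
            name = sprintf("%s_peak%d", tf, s))
        tfPeaks[[tf]] <- if (is.null(tfPeaks[[tf]])) pk else
            c(tfPeaks[[tf]], pk)
        chipPairs <- rbind(chipPairs, data.frame(tf = tf, target = tgt))
    }

    dacrs <- GenomicRanges::GRanges(seqlengths = c(chr1 = chromLen))
    for (s in seq_len(nPdi)) {
        g <- takeGenes(2L)
        tf <- geneIds[g[1]]; tgt <- geneIds[g[2]]
        mid <- tss[g[2]] + spacing %/% 2L    # intergenic, >1 kb from any TSS
        d <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(mid - 150L, mid + 149L),
            name = sprintf("dacr%d", s), seqlengths = c(chr1 = chromLen))
        S4Vectors::mcols(d)$name <- sprintf("dacr%d", s)
        dacrs <- c(dacrs, d)
        pk <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(mid - 100L, mid + 99L),
            name = sprintf("%s_dacrpeak%d", tf, s))
        tfPeaks[[tf]] <- if (is.null(tfPeaks[[tf]])) pk else
            c(tfPeaks[[tf]], pk)
        addLoop(c(mid - 200L, mid + 199L), anchorAt(g[2], -400, 399))
        loopPairs <- rbind(loopPairs, data.frame(
            geneA = tf, geneB = tgt, kind = "PDI"))
    }

    anchorGr <- function(m) {
        if (nrow(m) == 0)
            GenomicRanges::GRanges(seqlengths = c(chr1 = chromLen))
        else GenomicRanges::GRanges("chr1",
            IRanges::IRanges(m[, 1], m[, 2]),
            seqlengths = c(chr1 = chromLen))
    }
    loops <- S4Vectors::Pairs(anchorGr(anchors1), anchorGr(anchors2))

    truth <- methods::new("SynTruth",
        trueTime = numeric(), cellType = character(),
        lowQuality = data.frame(), dynamicLabels = character(),
        motifPositions = mp, loopPairs = loopPairs, chipPairs = chipPairs)

    list(annotation = ann, mhs = mhs, dacrs = dacrs, tfPeaks = tfPeaks,
         loops = loops, promoters = promoters, coverage = covGr,
         chromLen = chromLen, truth = truth)
}

# reverse complement of a plain character motif string
revcompStr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
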