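# Epigenomic integration: TSS metagene profiles, PWM scanning and motif
# enrichment within MNase-hypersensitive sites, footprint aggregation,
# and loop/peak-based regulatory-network construction.

# TSS (1-based) of each gene in an annotation GRanges (strand-aware).
tssOf <- function(ann) {
    ifelse(as.character(GenomicRanges::strand(ann)) == "-",
           GenomicRanges::end(ann), GenomicRanges::start(ann))
}

# Promoter windows [TSS - halfwidth, TSS + halfwidth) as GRanges.
promoterWindows <- function(ann, halfwidth = 1000) {
    tss <- tssOf(ann)
    GenomicRanges::GRanges(
        GenomicRanges::seqnames(ann),
        IRanges::IRanges(pmax(1L, tss - as.integer(halfwidth)),
                         tss + as.integer(halfwidth) - 1L),
        gene_id = ann$gene_id)
}

#' TSS-centered metagene coverage profile
#'
#' Averages normalized coverage in `bin`-bp bins across the window
#' `[TSS - flank, TSS + flank)` of each gene, oriented 5' to 3'
#' (minus-strand windows reversed), then averages genes within each
#' group. Coverage is normalized to counts per million of the track
#' total. Genes whose window exceeds the chromosome bounds are skipped.
#'
#' @param coverage GRanges with a `score` column (bedGraph semantics)
#'   and seqlengths, or a path to a bedGraph file.
#' @param ann annotation GRanges with `gene_id` (TSS = start for `+`,
#'   end for `-` strand).
#' @param groups named character: gene id to group label; default one
#'   group `"all"` covering every gene.
#' @param flank half-window in bp (default 1500).
#' @param bin bin width in bp (default 100).
#' @return A [MetaProfile-class] object.
#' @export
metageneProfile <- function(coverage, ann, groups = NULL, flank = 1500,
                            bin = 100) {
    if (is.character(coverage))
        coverage <- rtracklayer::import(coverage, format = "bedGraph")
    if (is.null(groups))
        groups <- stats::setNames(rep("all", length(ann)), ann$gene_id)
    nBins <- as.integer(2 * flank / bin)
    covRle <- GenomicRanges::coverage(coverage, weight = "score")
    total <- sum(vapply(covRle, function(r)
        sum(as.numeric(S4Vectors::runValue(r)) *
            S4Vectors::runLength(r)), numeric(1)))
    nf <- if (total > 0) 1e6 / total else 1
    tss <- tssOf(ann)
    strands <- as.character(GenomicRanges::strand(ann))
    chroms <- as.character(GenomicRanges::seqnames(ann))
    lens <- GenomeInfoDb::seqlengths(coverage)
    grpLevels <- sort(unique(groups))
    acc <- matrix(0, length(grpLevels), nBins,
                  dimnames = list(grpLevels, NULL))
    nG <- stats::setNames(integer(length(grpLevels)), grpLevels)
    skipped <- character()
    for (i in seq_along(ann)) {
        gid <- ann$gene_id[i]
        grp <- groups[gid]
        if (is.na(grp)) next
        lo <- tss[i] - flank
        hi <- tss[i] + flank - 1L
        chr <- chroms[i]
        if (!chr %in% names(covRle) || lo < 1 ||
            (!is.na(lens[chr]) && hi > lens[chr])) {
            skipped <- c(skipped, gid)
            next
        }
        v <- as.numeric(S4Vectors::window(covRle[[chr]], lo, hi))
        bins <- colMeans(matrix(v, nrow = bin))
        if (strands[i] == "-") bins <- rev(bins)
        acc[grp, ] <- acc[grp, ] + bins
        nG[grp] <- nG[grp] + 1L
    }
    prof <- sweep(acc, 1, pmax(nG, 1L), "/") * nf
    obj <- methods::new("MetaProfile", profile = prof,
                        flank = as.numeric(flank), bin = as.numeric(bin),
                        nGenes = nG)
    attr(obj, "skipped") <- skipped
    obj
}

# log-odds score matrix of a PWM: 4 x width, N row = 0.
pwmLogOdds <- function(pwm, eps = 1e-9) {
    lo <- t(log2((pwm@mat + eps) / rep(pwm@background + eps,
                                       each = nrow(pwm@mat))))
    rownames(lo) <- c("A", "C", "G", "T")
    rbind(lo, N = 0)
}

# score all offsets of one sequence (character) against a 5 x w log-odds
scanOneStrand <- function(seqChr, lo) {
    w <- ncol(lo)
    bases <- strsplit(seqChr, "")[[1]]
    idx <- match(bases, c("A", "C", "G", "T"))
    idx[is.na(idx)] <- 5L
    L <- length(idx)
    if (L < w) return(numeric(0))
    nOff <- L - w + 1L
    sc <- numeric(nOff)
    for (k in seq_len(w))
        sc <- sc + lo[cbind(idx[k:(k + nOff - 1L)], k)]
    sc
}

#' Scan sequences with a PWM
#'
#' Log-odds scanning of both strands of each sequence. Positions with
#' non-ACGT letters contribute a log-odds of zero (background). Hits with
#' score at or above the threshold are reported with 1-based offsets on
#' the forward sequence, sorted by sequence then position.
#'
#' @param pwm a [Pwm-class] object.
#' @param seqs a named [Biostrings::DNAStringSet] (or named character
#'   vector) of sequences.
#' @param threshold log-odds score threshold; default 80% of the maximum
#'   achievable score.
#' @return data.frame `seq`, `offset`, `strand`, `score`.
#' @export
scanMotifs <- function(pwm, seqs, threshold = NULL) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    lo <- pwmLogOdds(pwm)
    w <- ncol(lo)
    if (is.null(threshold))
        threshold <- 0.8 * sum(apply(lo[1:4, , drop = FALSE], 2, max))
    out <- list()
    for (s in seq_along(seqs)) {
        fwd <- as.character(seqs[[s]])
        L <- nchar(fwd)
        if (L < w) next
        scF <- scanOneStrand(fwd, lo)
        rc <- as.character(Biostrings::reverseComplement(seqs[[s]]))
        scR <- scanOneStrand(rc, lo)
        hitF <- which(scF >= threshold)
        hitR <- which(scR >= threshold)
        if (length(hitF))
            out[[length(out) + 1L]] <- data.frame(
                seq = names(seqs)[s], offset = hitF, strand = "+",
                score = scF[hitF])
        if (length(hitR))
            out[[length(out) + 1L]] <- data.frame(
                seq = names(seqs)[s], offset = L - w + 2L - hitR,
                strand = "-", score = scR[hitR])
    }
    if (length(out) == 0)
        return(data.frame(seq = character(), offset = integer(),
                          strand = character(), score = numeric()))
    res <- do.call(rbind, out)
    res <- res[order(res$seq, res$offset, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Motif enrichment between sequence sets
#'
#' For each PWM, counts sequences with at least one hit in the foreground
#' and background sets, forms the 2x2 table and computes a one-sided
#' Fisher exact p-value (enrichment in the foreground), with
#' Benjamini-Hochberg correction across motifs. Background sequences
#' also present in the foreground are dropped with a warning.
#'
#' @param pwms list of [Pwm-class] objects.
#' @param fgSeqs foreground [Biostrings::DNAStringSet] (named).
#' @param bgSeqs background [Biostrings::DNAStringSet] (named).
#' @param threshold passed to [scanMotifs()] (default per-motif 80% of
#'   maximum score).
#' @return data.frame per motif: hit counts, odds ratio, `p`, `q`,
#'   ordered by p-value.
#' @export
motifEnrichment <- function(pwms, fgSeqs, bgSeqs, threshold = NULL) {
    if (length(fgSeqs) == 0 || length(bgSeqs) == 0)
        stop("foreground and background must be non-empty")
    dup <- intersect(names(fgSeqs), names(bgSeqs))
    if (length(dup)) {
        warning(length(dup), " background sequence(s) also in ",
                "foreground removed")
        bgSeqs <- bgSeqs[setdiff(names(bgSeqs), dup)]
    }
    rows <- lapply(pwms, function(pwm) {
        fgHit <- length(unique(scanMotifs(pwm, fgSeqs, threshold)$seq))
        bgHit <- length(unique(scanMotifs(pwm, bgSeqs, threshold)$seq))
        tab <- matrix(c(fgHit, length(fgSeqs) - fgHit,
                        bgHit, length(bgSeqs) - bgHit), 2)
        ft <- stats::fisher.test(tab, alternative = "greater")
        data.frame(motif = pwm@name, fgHit = fgHit,
                   fgTotal = length(fgSeqs), bgHit = bgHit,
                   bgTotal = length(bgSeqs),
                   oddsRatio = unname(ft$estimate), p = ft$p.value)
    })
    res <- do.call(rbind, rows)
    res$q <- stats::p.adjust(res$p, method = "BH")
    res <- res[order(res$p, res$motif), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Map promoter-relative motif hits to genomic coordinates
#'
#' Converts hits from [scanMotifs()] on promoter sequences (as produced
#' by [simulateGenomeTracks()]: `promWidth` bp upstream of the TSS,
#' written 5' to 3') into genomic intervals with strand.
#'
#' @param hits data.frame from [scanMotifs()].
#' @param ann annotation GRanges with `gene_id`.
#' @param motifWidth motif width in bp.
#' @param promWidth promoter sequence length used when extracting.
#' @return data.frame `chrom`, `start`, `end` (1-based closed),
#'   `strand` (genomic), `seq`.
#' @export
motifHitsToGenome <- function(hits, ann, motifWidth, promWidth = 500) {
    tss <- stats::setNames(tssOf(ann), ann$gene_id)
    gstr <- stats::setNames(as.character(GenomicRanges::strand(ann)),
                            ann$gene_id)
    chrom <- stats::setNames(
        as.character(GenomicRanges::seqnames(ann)), ann$gene_id)
    plus <- gstr[hits$seq] == "+"
    start <- ifelse(plus,
        tss[hits$seq] - promWidth + hits$offset - 1L,
        tss[hits$seq] + promWidth - (hits$offset - 1L) - motifWidth + 1L)
    genomicStrand <- ifelse(plus == (hits$strand == "+"), "+", "-")
    data.frame(chrom = unname(chrom[hits$seq]),
               start = as.integer(start),
               end = as.integer(start + motifWidth - 1L),
               strand = genomicStrand, seq = hits$seq)
}

#' Aggregate a nuclease footprint around motif sites
#'
#' Extracts per-base coverage in a window of `w` bp on each side of every
#' motif occurrence, reverses minus-strand sites, and averages across
#' sites. A bound factor appears as a coverage dip over the motif span.
#'
#' @param coverage GRanges with `score` (bedGraph semantics) or bedGraph
#'   path.
#' @param hits data.frame of genomic motif sites (`chrom`, `start`,
#'   `end`, `strand`), e.g. from [motifHitsToGenome()].
#' @param w flank width in bp (default 100; `w = 0` profiles the motif
#'   span only).
#' @return A [FootprintProfile-class] object.
#' @export
aggregateFootprint <- function(coverage, hits, w = 100) {
    if (is.character(coverage))
        coverage <- rtracklayer::import(coverage, format = "bedGraph")
    if (nrow(hits) == 0) stop("no mappable motif sites")
    widths <- hits$end - hits$start + 1L
    if (length(unique(widths)) != 1)
        stop("all sites must have the same motif width")
    mw <- widths[1]
    covRle <- GenomicRanges::coverage(coverage, weight = "score")
    lens <- GenomeInfoDb::seqlengths(coverage)
    prof <- numeric(2L * w + mw)
    n <- 0L
    for (i in seq_len(nrow(hits))) {
        chr <- hits$chrom[i]
        lo <- hits$start[i] - w
        hi <- hits$end[i] + w
        if (!chr %in% names(covRle) || lo < 1 ||
            (!is.na(lens[chr]) && hi > lens[chr])) next
        v <- as.numeric(S4Vectors::window(covRle[[chr]], lo, hi))
        if (!is.null(hits$strand) && hits$strand[i] == "-") v <- rev(v)
        prof <- prof + v
        n <- n + 1L
    }
    if (n == 0L) stop("no mappable motif sites")
    methods::new("FootprintProfile", profile = prof / n, nSites = n,
                 motifWidth = as.integer(mw), w = as.integer(w))
}

#' Build the typed multi-omic regulatory network
#'
#' Constructs four edge types with full provenance:
#' \describe{
#'   \item{chip_direct}{TF to gene when a TF ChIP peak overlaps the
#'     gene's promoter window (TSS +/- `promoterHalfwidth`).}
#'   \item{PPI}{gene to gene when both promoters map onto loop anchors
#'     connected by a chain of at most `maxChain` loops whose anchors
#'     overlap ("consecutive" loops).}
#'   \item{PDI}{TF to gene when a TF peak overlaps a distal accessible
#'     region (dACR) that is loop-anchored to the gene's promoter.}
#'   \item{predicted}{edges imported from the consensus network.}
#' }
#'
#' @param ann annotation GRanges with `gene_id`.
#' @param tfPeaks named list of GRanges (one per TF; names are TF gene
#'   ids).
#' @param mhs MNase-hypersensitive peaks (GRanges; carried for
#'   provenance, not an edge rule).
#' @param dacrs dACR GRanges (with `name` if available).
#' @param loops [S4Vectors::Pairs] of anchor GRanges.
#' @param consensus optional [ConsensusNetwork-class].
#' @param promoterHalfwidth promoter half-window in bp (default 1000).
#' @param maxChain maximum loop-chain length for PPI (default 2).
#' @return A [RegulatoryNetwork-class] object.
#' @export
buildRegulatoryNetwork <- function(ann, tfPeaks = list(), mhs = NULL,
                                   dacrs = NULL, loops = NULL,
                                   consensus = NULL,
                                   promoterHalfwidth = 1000,
                                   maxChain = 2) {
    prom <- promoterWindows(ann, promoterHalfwidth)
    edges <- list()

    # chip_direct: TF peak within promoter window
    for (tf in names(tfPeaks)) {
        ov <- GenomicRanges::findOverlaps(tfPeaks[[tf]], prom)
        if (length(ov) == 0) next
        pk <- S4Vectors::queryHits(ov)
        gid <- prom$gene_id[S4Vectors::subjectHits(ov)]
        keep <- gid != tf
        if (!any(keep)) next
        pkName <- if (!is.null(tfPeaks[[tf]]$name))
            tfPeaks[[tf]]$name[pk] else paste0("peak", pk)
        edges[[length(edges) + 1L]] <- data.frame(
            from = tf, to = gid[keep], type = "chip_direct",
            provenance = paste0("peak=", pkName[keep]))
    }

    # PPI: promoters on anchors joined by <= maxChain anchor-overlapping
    # loops
    if (!is.null(loops) && length(loops) > 0) {
        a1 <- S4Vectors::first(loops)
        a2 <- S4Vectors::second(loops)
        anchors <- c(a1, a2)
        nL <- length(loops)
        merged <- GenomicRanges::reduce(anchors)
        nodeOf <- GenomicRanges::findOverlaps(anchors, merged,
                                              select = "first")
        node1 <- nodeOf[seq_len(nL)]
        node2 <- nodeOf[nL + seq_len(nL)]
        g <- igraph::graph_from_edgelist(cbind(node1, node2),
                                         directed = FALSE)
        if (igraph::vcount(g) < length(merged))
            g <- igraph::add_vertices(g, length(merged) -
                                          igraph::vcount(g))
        # promoter -> merged anchor attachment
        pov <- GenomicRanges::findOverlaps(prom, merged)
        att <- split(S4Vectors::subjectHits(pov),
                     prom$gene_id[S4Vectors::queryHits(pov)])
        genesAtt <- names(att)
        if (length(genesAtt) > 1) {
            dmat <- igraph::distances(g)
            loopIds <- paste0("loop", seq_len(nL))
            for (i in seq_along(genesAtt)[-length(genesAtt)])
                for (j in (i + 1L):length(genesAtt)) {
                    ni <- att[[i]]; nj <- att[[j]]
                    dd <- min(dmat[ni, nj, drop = FALSE])
                    if (is.finite(dd) && dd >= 1 && dd <= maxChain) {
                        # provenance: loops on one shortest chain
                        sp <- igraph::shortest_paths(
                            g, from = ni[1], to = nj[which.min(
                                dmat[ni[1], nj])], output = "epath")
                        eIds <- as.integer(sp$epath[[1]])
                        lid <- loopIds[eIds]
                        edges[[length(edges) + 1L]] <- data.frame(
                            from = genesAtt[i], to = genesAtt[j],
                            type = "PPI",
                            provenance = paste0(
                                "loops=", paste(lid, collapse = "+")))
                    }
                }
        }
    }

    # PDI: TF peak on a dACR looped to a gene promoter
    if (!is.null(dacrs) && length(dacrs) > 0 && !is.null(loops) &&
        length(loops) > 0) {
        a1 <- S4Vectors::first(loops)
        a2 <- S4Vectors::second(loops)
        dacrName <- if (!is.null(dacrs$name)) dacrs$name else
            paste0("dacr", seq_along(dacrs))
        for (tf in names(tfPeaks)) {
            dov <- GenomicRanges::findOverlaps(tfPeaks[[tf]], dacrs)
            if (length(dov) == 0) next
            for (h in seq_along(dov)) {
                di <- S4Vectors::subjectHits(dov)[h]
                d <- dacrs[di]
                for (side in 1:2) {
                    near <- if (side == 1) a1 else a2
                    far <- if (side == 1) a2 else a1
                    lov <- GenomicRanges::findOverlaps(d, near)
                    for (li in S4Vectors::subjectHits(lov)) {
                        gov <- GenomicRanges::findOverlaps(far[li], prom)
                        gid <- prom$gene_id[S4Vectors::subjectHits(gov)]
                        gid <- setdiff(gid, tf)
                        if (length(gid))
                            edges[[length(edges) + 1L]] <- data.frame(
                                from = tf, to = gid, type = "PDI",
                                provenance = sprintf(
                                    "peak=%s;dacr=%s;loop=loop%d",
                                    tf, dacrName[di], li))
                    }
                }
            }
        }
    }

    if (!is.null(consensus) && nrow(networkEdges(consensus)) > 0) {
        ce <- networkEdges(consensus)
        edges[[length(edges) + 1L]] <- data.frame(
            from = ce$regulator, to = ce$target, type = "predicted",
            provenance = sprintf("consensus_weight=%.6g", ce$weight))
    }

    tab <- if (length(edges)) unique(do.call(rbind, edges)) else
        data.frame(from = character(), to = character(),
                   type = character(), provenance = character())
    tab <- tab[order(tab$type, tab$from, tab$to), , drop = FALSE]
    rownames(tab) <- NULL
    methods::new("RegulatoryNetwork", edges = tab)
}

#' Re-validate the provenance of every network edge
#'
#' Checks that each edge's recorded evidence still satisfies the rule
#' that created it: chip_direct peaks overlap the target promoter, PPI
#' loop chains connect the two promoters, PDI peak/dACR/loop triples
#' hold, predicted edges cite a weight.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param ann,tfPeaks,dacrs,loops the inputs used to build the network.
#' @param promoterHalfwidth promoter half-window used at build time.
#' @return logical vector, one per edge.
#' @export
validateProvenance <- function(net, ann, tfPeaks = list(), dacrs = NULL,
                               loops = NULL, promoterHalfwidth = 1000) {
    prom <- promoterWindows(ann, promoterHalfwidth)
    e <- networkEdges(net)
    vapply(seq_len(nrow(e)), function(i) {
        type <- e$type[i]
        if (type == "chip_direct") {
            pks <- tfPeaks[[e$from[i]]]
            if (is.null(pks)) return(FALSE)
            pw <- prom[prom$gene_id == e$to[i]]
            length(GenomicRanges::findOverlaps(pks, pw)) > 0
        } else if (type == "PPI") {
            lid <- as.integer(gsub("loop", "",
                strsplit(sub("loops=", "", e$provenance[i]), "\\+")[[1]]))
            sub <- loops[lid]
            # the cited chain must touch both promoters
            pa <- prom[prom$gene_id == e$from[i]]
            pb <- prom[prom$gene_id == e$to[i]]
            anch <- c(S4Vectors::first(sub), S4Vectors::second(sub))
            length(GenomicRanges::findOverlaps(pa, anch)) > 0 &&
                length(GenomicRanges::findOverlaps(pb, anch)) > 0
        } else if (type == "PDI") {
            pv <- strsplit(e$provenance[i], ";")[[1]]
            kv <- sub("^[^=]*=", "", pv)
            names(kv) <- sub("=.*$", "", pv)
            pks <- tfPeaks[[e$from[i]]]
            dacrName <- if (!is.null(dacrs$name)) dacrs$name else
                paste0("dacr", seq_along(dacrs))
            d <- dacrs[dacrName == kv["dacr"]]
            li <- as.integer(gsub("loop", "", kv["loop"]))
            lp <- loops[li]
            pw <- prom[prom$gene_id == e$to[i]]
            anch <- c(S4Vectors::first(lp), S4Vectors::second(lp))
            length(GenomicRanges::findOverlaps(pks, d)) > 0 &&
                length(GenomicRanges::findOverlaps(d, anch)) > 0 &&
                length(GenomicRanges::findOverlaps(pw, anch)) > 0
        } else if (type == "predicted") {
            grepl("consensus_weight=", e$provenance[i])
        } else FALSE
    }, logical(1))
}

#' Classify target genes by cofactor co-binding
#'
#' Splits a target list into genes whose promoter window (TSS +/-
#' `halfwidth`) overlaps at least one cofactor peak and the complement;
#' the union equals the input. Used, e.g., to separate HSF1-bound genes
#' by the presence of a COL8 peak.
#'
#' @param targets character vector of gene ids (if `NULL`, derived as
#'   genes with a `peaksPrimary` peak in their promoter window).
#' @param peaksPrimary optional GRanges of the primary factor's peaks.
#' @param peaksCofactor GRanges of cofactor peaks.
#' @param ann annotation GRanges with `gene_id`.
#' @param halfwidth promoter half-window in bp (default 1000).
#' @return list `withCofactor`, `withoutCofactor` (disjoint, union =
#'   targets).
#' @export
classifyTargetsByCofactor <- function(targets = NULL, peaksPrimary = NULL,
                                      peaksCofactor, ann,
                                      halfwidth = 1000) {
    prom <- promoterWindows(ann, halfwidth)
    if (is.null(targets)) {
        if (is.null(peaksPrimary))
            stop("either targets or peaksPrimary must be given")
        ov <- GenomicRanges::findOverlaps(peaksPrimary, prom)
        targets <- unique(prom$gene_id[S4Vectors::subjectHits(ov)])
    }
    missing <- setdiff(targets, ann$gene_id)
    if (length(missing))
        stop("targets absent from annotation: ",
             paste(missing, collapse = ", "))
    pw <- prom[match(targets, prom$gene_id)]
    hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(pw, peaksCofactor)))
    list(withCofactor = targets[sort(hit)],
         withoutCofactor = targets[setdiff(seq_along(targets),
                                           hit)])
}
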