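mkCoverage <- function(chromLen, segs) {
    # segs: data.frame(start, end, score); baseline 0 elsewhere
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(segs$start, segs$end), score = segs$score,
        seqlengths = c(chr1 = chromLen))
    gr
}

mkAnn <- function(tss, strand, chromLen = 20000) {
    GenomicRanges::GRanges("chr1",
        IRanges::IRanges(ifelse(strand == "+", tss, tss - 99L),
                         ifelse(strand == "+", tss + 99L, tss)),
        strand = strand,
        gene_id = sprintf("gene%02d", seq_along(tss)),
        seqlengths = c(chr1 = chromLen))
}

test_that("metagene profiles have 2*flank/bin bins and orient by strand", {
    ann <- mkAnn(c(5000L, 12000L), c("+", "-"))
    # uniform unit coverage -> flat profile at the normalized constant
    unif <- mkCoverage(20000, data.frame(start = 1, end = 20000,
                                         score = 1))
    mp <- metageneProfile(unif, ann, flank = 1500, bin = 100)
    expect_equal(ncol(mp@profile), 30L)
    expect_true(all(abs(mp@profile - 1e6 / 20000) < 1e-9))

    # signal strictly downstream of the minus-strand TSS appears in the
    # oriented downstream half (bins 16..30)
    sig <- mkCoverage(20000, data.frame(start = 11000, end = 11999,
                                        score = 5))
    grp <- stats::setNames(c("up", "dn"), ann$gene_id)
    mp2 <- metageneProfile(sig, ann, groups = grp)
    dn <- mp2@profile["dn", ]
    expect_true(all(dn[16:25] > 0))     # signal spans TSS to TSS+1kb
    expect_true(all(dn[1:15] == 0))

    # a window exceeding the chromosome start is skipped and logged
    annEdge <- mkAnn(c(800L, 5000L), c("+", "+"))
    mp3 <- metageneProfile(unif, annEdge)
    expect_identical(attr(mp3, "skipped"), "gene01")
    expect_identical(unname(mp3@nGenes["all"]), 1L)
})

test_that("a strand-symmetric planted signal yields a palindromic profile", {
    ann <- mkAnn(c(5000L, 12000L), c("+", "-"))
    segs <- rbind(
        data.frame(start = 5000 - 500, end = 5000 + 499, score = 3),
        data.frame(start = 12000 - 500, end = 12000 + 499, score = 3))
    mp <- metageneProfile(mkCoverage(20000, segs), ann)
    prof <- mp@profile[1, ]
    expect_equal(unname(prof), unname(rev(prof)), tolerance = 1e-9)
})

test_that("PWM scanning finds consensus instances on both strands", {
    pwm <- hsfPwm()
    hit <- scanMotifs(pwm, c(s1 = paste0(strrep("C", 30), "AGAACCTTCT",
                                         strrep("G", 30))))
    expect_true(any(hit$seq == "s1" & hit$offset == 31))

    # non-palindromic motif: a reverse-complement insert reports "-"
    mat <- t(vapply(strsplit("ACGTAC", "")[[1]], function(b) {
        p <- rep(0.02, 4); p[match(b, c("A", "C", "G", "T"))] <- 0.94; p
    }, numeric(4)))
    rownames(mat) <- NULL
    np <- Pwm(mat, name = "np")
    seqMinus <- paste0(strrep("T", 20), "GTACGT", strrep("T", 20))
    hitM <- scanMotifs(np, c(m1 = seqMinus))
    expect_true(any(hitM$strand == "-" & hitM$offset == 21))

    # motif wider than the sequence: sequence skipped, no error
    expect_equal(nrow(scanMotifs(np, c(tiny = "ACG"))), 0L)

    # N positions score as background (contribution zero)
    withN <- paste0(strrep("C", 10), "AGAANNTTCT", strrep("C", 10))
    hitN <- scanMotifs(pwm, c(n1 = withN))
    expect_true(any(hitN$offset == 11))
})

test_that("scan hits match the exhaustive per-offset oracle", {
    set.seed(41)
    pwm <- hsfPwm()
    seqChr <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
    seqChr <- paste0(substr(seqChr, 1, 80), "AGAATGTTCT",
                     substr(seqChr, 91, 200))
    lo <- mesotraject:::pwmLogOdds(pwm)
    thr <- 0.5 * sum(apply(lo[1:4, ], 2, max))  # permissive: more hits
    got <- scanMotifs(pwm, c(t1 = seqChr), threshold = thr)
    want <- scanOracle(pwm, seqChr, thr)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$offset, got$strand),
                    paste(want$offset, want$strand))
    ord <- order(want$offset, want$strand)
    expect_equal(got$score[order(got$offset, got$strand)],
                 want$score[ord], tolerance = 1e-9)
})

test_that("motif enrichment matches the hypergeometric tail", {
    set.seed(42)
    pwm <- hsfPwm()
    inst <- "AGAACCTTCT"
    rnd <- function() paste(sample(c("A", "C", "G", "T"), 60,
                                   replace = TRUE), collapse = "")
    fg <- stats::setNames(vapply(1:20, function(i)
        paste0(substr(rnd(), 1, 25), inst, substr(rnd(), 36, 60)),
        character(1)), paste0("f", 1:20))
    bg <- stats::setNames(vapply(1:20, function(i) rnd(), character(1)),
                          paste0("b", 1:20))
    res <- motifEnrichment(list(pwm), fg, bg)
    # all-20 vs 0-of-20: the minimal p for the table
    expect_equal(res$fgHit, 20L)
    expect_equal(res$bgHit, 0L)
    expect_equal(res$p, 1 / choose(40, 20), tolerance = 1e-9)

    # equal frequencies are unenriched
    resEq <- motifEnrichment(list(pwm), fg, fg2 <- stats::setNames(
        fg, paste0("g", 1:20)))
    expect_gte(resEq$p, 0.5)

    # 12/20 vs 3/20 equals the closed-form hypergeometric sum
    f2 <- c(fg[1:12], bg[1:8])
    names(f2) <- paste0("x", 1:20)
    b2 <- c(fg[13:15], bg[9:20], bg[1:5])
    names(b2) <- paste0("y", 1:20)
    res2 <- motifEnrichment(list(pwm), f2, b2)
    expect_equal(res2$fgHit, 12L)
    expect_equal(res2$bgHit, 3L)
    pOracle <- sum(stats::dhyper(12:15, 15, 25, 20))
    expect_equal(res2$p, pOracle, tolerance = 1e-9)

    # overlapping sequences are deduplicated from the background
    expect_warning(motifEnrichment(list(pwm), fg, c(bg, fg[1])),
                   "foreground")
})

test_that("footprint aggregation dips over the planted motif span", {
    tr <- simulateGenomeTracks(seed = 5)
    pwm <- hsfPwm()
    hits <- scanMotifs(pwm, tr$promoters)
    ghits <- motifHitsToGenome(hits, tr$annotation, motifWidth = 10,
                               promWidth = 500)
    fp <- aggregateFootprint(tr$coverage, ghits, w = 100)
    expect_length(fp@profile, 2 * 100 + 10)
    expect_true(which.min(fp@profile) %in% 101:110)
    expect_equal(fp@nSites, nrow(ghits))

    # w = 0 profiles the motif span only
    fp0 <- aggregateFootprint(tr$coverage, ghits, w = 0)
    expect_length(fp0@profile, 10L)

    expect_error(aggregateFootprint(tr$coverage, ghits[0, ]),
                 "mappable")
})

test_that("loop chains build PPI edges across shared anchors", {
    # genes at 5 kb, 12 kb, 19 kb; loops A-B and B-C share anchor B
    ann <- mkAnn(c(5000L, 12000L, 19000L), c("+", "+", "+"), 25000)
    loops <- S4Vectors::Pairs(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(
            c(4800, 11900), c(5200, 12300))),
        GenomicRanges::GRanges("chr1", IRanges::IRanges(
            c(11700, 18800), c(12100, 19200))))
    net <- buildRegulatoryNetwork(ann, loops = loops, maxChain = 2)
    e <- networkEdges(net)
    expect_setequal(pairKeys(e$from, e$to),
                    pairKeys(c("gene01", "gene02", "gene01"),
                             c("gene02", "gene03", "gene03")))
    # chain length 2 is the limit: maxChain = 1 drops the A-C edge
    net1 <- buildRegulatoryNetwork(ann, loops = loops, maxChain = 1)
    expect_equal(nrow(networkEdges(net1)), 2L)

    # no peaks and no loops leaves only predicted edges
    cons <- methods::new("ConsensusNetwork", edges = data.frame(
        regulator = "gene01", target = "gene02", weight = 0.4,
        tom = 0.9), cutoff = 0.1)
    netP <- buildRegulatoryNetwork(ann, consensus = cons)
    expect_identical(unique(networkEdges(netP)$type), "predicted")
})

test_that("planted peaks and loops are reconstructed exactly", {
    tr <- simulateGenomeTracks(seed = 6)
    truth <- tr$truth
    net <- buildRegulatoryNetwork(tr$annotation, tr$tfPeaks, tr$mhs,
                                  tr$dacrs, tr$loops)
    e <- networkEdges(net)
    ppiT <- truth@loopPairs[truth@loopPairs$kind == "PPI", ]
    ppiG <- e[e$type == "PPI", ]
    expect_identical(pairKeys(ppiG$from, ppiG$to),
                     pairKeys(ppiT$geneA, ppiT$geneB))
    pdiT <- truth@loopPairs[truth@loopPairs$kind == "PDI", ]
    pdiG <- e[e$type == "PDI", ]
    expect_setequal(paste(pdiG$from, pdiG$to),
                    paste(pdiT$geneA, pdiT$geneB))
    chipG <- e[e$type == "chip_direct", ]
    expect_setequal(paste(chipG$from, chipG$to),
                    paste(truth@chipPairs$tf, truth@chipPairs$target))
    # every edge's provenance re-validates
    expect_true(all(validateProvenance(net, tr$annotation, tr$tfPeaks,
                                       tr$dacrs, tr$loops)))
})

test_that("promoter-overlap calls agree with a brute-force oracle", {
    set.seed(43)
    ann <- mkAnn(as.integer(seq(3000, 57000, length.out = 12)),
                 rep(c("+", "-"), 6), 60000)
    peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = sample(1000:58000, 300, replace = TRUE),
        width = sample(100:600, 300, replace = TRUE)),
        seqlengths = c(chr1 = 60000))
    peaks$name <- paste0("p", seq_along(peaks))
    net <- buildRegulatoryNetwork(ann, tfPeaks = list(TFX = peaks),
                                  promoterHalfwidth = 1000)
    got <- networkEdges(net)
    got <- got[got$type == "chip_direct", ]
    # brute force: 1-based closed interval intersection per gene
    tss <- ifelse(as.character(GenomicRanges::strand(ann)) == "-",
                  GenomicRanges::end(ann), GenomicRanges::start(ann))
    hitGenes <- character()
    for (i in seq_along(ann)) {
        lo <- tss[i] - 1000; hi <- tss[i] + 999
        for (j in seq_along(peaks)) {
            ps <- GenomicRanges::start(peaks)[j]
            pe <- GenomicRanges::end(peaks)[j]
            if (ps <= hi && pe >= lo) {
                hitGenes <- c(hitGenes, ann$gene_id[i])
                break
            }
        }
    }
    expect_setequal(unique(got$to), hitGenes)
})

test_that("cofactor classification splits targets exactly", {
    ann <- mkAnn(c(5000L, 12000L, 19000L), c("+", "-", "+"), 25000)
    cof <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(5400, 5600))   # TSS1 + ~500
    res <- classifyTargetsByCofactor(
        targets = ann$gene_id, peaksCofactor = cof, ann = ann)
    expect_identical(res$withCofactor, "gene01")
    expect_setequal(res$withoutCofactor, c("gene02", "gene03"))
    expect_setequal(c(res$withCofactor, res$withoutCofactor),
                    ann$gene_id)

    # no cofactor peaks: everything in the second subset
    none <- GenomicRanges::GRanges()
    res2 <- classifyTargetsByCofactor(targets = ann$gene_id,
                                      peaksCofactor = none, ann = ann)
    expect_length(res2$withCofactor, 0L)
    expect_setequal(res2$withoutCofactor, ann$gene_id)

    # subset sizes match a brute-force overlap oracle on random peaks
    set.seed(44)
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        sample(1000:24000, 40), width = 200))
    res3 <- classifyTargetsByCofactor(targets = ann$gene_id,
                                      peaksCofactor = pk, ann = ann)
    tss <- c(5000, 12000, 19000)
    inProm <- vapply(seq_along(tss), function(i)
        any(GenomicRanges::start(pk) <= tss[i] + 999 &
            GenomicRanges::end(pk) >= tss[i] - 1000), logical(1))
    expect_length(res3$withCofactor, sum(inProm))

    expect_error(classifyTargetsByCofactor(
        targets = "ghost", peaksCofactor = pk, ann = ann), "absent")
})
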