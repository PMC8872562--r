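# Readers and writers for the standard formats the pipeline consumes and
# emits: 10x-style MTX triplets, GFF3/BED/bedGraph (via rtracklayer),
# BEDPE, FASTA (via Biostrings), MEME-format motifs, and network TSV/SIF.

#' Read a 10x-style count matrix directory
#'
#' Expects `matrix.mtx` (MatrixMarket, 1-based indices), `barcodes.tsv`
#' (one barcode per line) and `features.tsv` (gene id, gene name, and
#' optionally a logical mitochondrial flag column; otherwise
#' mitochondrial genes are recognized by a `mito`/`MT-` id prefix).
#'
#' @param dir directory containing the triplet.
#' @return A [MesoCounts-class] object.
#' @export
readCounts <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    bc <- file.path(dir, "barcodes.tsv")
    ft <- file.path(dir, "features.tsv")
    if (!all(file.exists(mtx, bc, ft)))
        stop("matrix.mtx, barcodes.tsv and features.tsv are required")
    m <- Matrix::readMM(mtx)
    barcodes <- readLines(bc)
    features <- utils::read.table(ft, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)
    if (nrow(m) != nrow(features))
        stop("dimension mismatch: matrix has ", nrow(m),
             " rows but features.tsv has ", nrow(features), " lines")
    if (ncol(m) != length(barcodes))
        stop("dimension mismatch: matrix has ", ncol(m),
             " columns but barcodes.tsv has ", length(barcodes), " lines")
    cts <- as.matrix(m)
    dimnames(cts) <- list(features[[1]], barcodes)
    mito <- if (ncol(features) >= 3) as.logical(features[[3]]) else NULL
    MesoCounts(cts, mito = if (!is.null(mito)) features[[1]][mito])
}

#' Write a count matrix as a 10x-style triplet
#'
#' @param x a [MesoCounts-class] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- SummarizedExperiment::assay(x, "counts")
    Matrix::writeMM(methods::as(Matrix::Matrix(cts, sparse = TRUE),
                                "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
    utils::write.table(
        data.frame(rownames(x), rownames(x), mitoMask(x)),
        file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' Write loops as BEDPE
#'
#' Six-column BEDPE (0-based half-open anchors), one loop per line.
#'
#' @param loops [S4Vectors::Pairs] of anchor GRanges.
#' @param path output file.
#' @export
writeLoops <- function(loops, path) {
    a1 <- S4Vectors::first(loops)
    a2 <- S4Vectors::second(loops)
    df <- data.frame(
        chrom1 = as.character(GenomicRanges::seqnames(a1)),
        start1 = GenomicRanges::start(a1) - 1L,
        end1 = GenomicRanges::end(a1),
        chrom2 = as.character(GenomicRanges::seqnames(a2)),
        start2 = GenomicRanges::start(a2) - 1L,
        end2 = GenomicRanges::end(a2))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read loops from BEDPE
#'
#' @param path BEDPE file (>= 6 columns, 0-based half-open).
#' @return [S4Vectors::Pairs] of anchor GRanges (1-based closed).
#' @export
readLoops <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    S4Vectors::Pairs(
        GenomicRanges::GRanges(df[[1]],
            IRanges::IRanges(df[[2]] + 1L, df[[3]])),
        GenomicRanges::GRanges(df[[4]],
            IRanges::IRanges(df[[5]] + 1L, df[[6]])))
}

#' Write PWMs in MEME text format
#'
#' Minimal MEME motif format (version 4 header, background frequencies,
#' one letter-probability matrix per motif).
#'
#' @param pwms list of [Pwm-class] objects.
#' @param path output file.
#' @export
writeMotifs <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    bg <- pwms[[1]]@background
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "Background letter frequencies",
                 sprintf("A %.5f C %.5f G %.5f T %.5f",
                         bg[1], bg[2], bg[3], bg[4]), ""), con)
    for (p in pwms) {
        writeLines(sprintf("MOTIF %s", p@name), con)
        writeLines(sprintf(
            "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            nrow(p@mat)), con)
        for (i in seq_len(nrow(p@mat)))
            writeLines(sprintf(" %.6f %.6f %.6f %.6f", p@mat[i, 1],
                               p@mat[i, 2], p@mat[i, 3], p@mat[i, 4]),
                       con)
        writeLines("", con)
    }
    invisible(path)
}

#' Read PWMs from MEME text format
#'
#' @param path MEME-format motif file.
#' @return list of [Pwm-class] objects.
#' @export
readMotifs <- function(path) {
    lines <- readLines(path)
    bg <- rep(0.25, 4)
    bgLine <- grep("^A [0-9.]+ C ", lines, value = TRUE)
    if (length(bgLine))
        bg <- as.numeric(strsplit(bgLine[1], " +")[[1]][c(2, 4, 6, 8)])
    starts <- grep("^MOTIF ", lines)
    lapply(starts, function(s) {
        name <- strsplit(lines[s], " +")[[1]][2]
        hdr <- grep("letter-probability matrix", lines)
        hdr <- hdr[hdr > s][1]
        w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
        mat <- do.call(rbind, lapply(lines[(hdr + 1):(hdr + w)],
            function(l) as.numeric(strsplit(trimws(l), " +")[[1]])))
        Pwm(mat, background = bg, name = name)
    })
}

# id escaping for network files: percent, space and tab are the only
# characters that collide with the TSV/SIF delimiters. Percent is
# escaped first so decoding (reverse order) is unambiguous.
escapeId <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(" ", "%20", x, fixed = TRUE)
    gsub("\t", "%09", x, fixed = TRUE)
}
unescapeId <- function(x) {
    x <- gsub("%09", "\t", x, fixed = TRUE)
    x <- gsub("%20", " ", x, fixed = TRUE)
    gsub("%25", "%", x, fixed = TRUE)
}

#' Export a network to TSV or SIF
#'
#' TSV carries all edge columns with a header; SIF encodes the edge type
#' in the relation column (`a type b`, whitespace-separated, ids
#' URL-escaped so they survive a round trip).
#'
#' @param net a [ConsensusNetwork-class], [RegulatoryNetwork-class] or
#'   [CoexprNetwork-class].
#' @param path output file.
#' @param format `"tsv"` or `"sif"`.
#' @param allowEmpty write an empty file instead of erroring when the
#'   network has no edges.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("tsv", "sif"),
                          allowEmpty = TRUE) {
    format <- match.arg(format)
    e <- networkEdges(net)
    if (nrow(e) == 0 && !allowEmpty) stop("network is empty")
    if (format == "tsv") {
        out <- e
        out[[1]] <- escapeId(out[[1]])
        out[[2]] <- escapeId(out[[2]])
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        type <- if ("type" %in% names(e)) e$type else
            rep("edge", nrow(e))
        writeLines(paste(escapeId(e[[1]]), type, escapeId(e[[2]])),
                   path)
    }
    invisible(path)
}

#' Read a network edge file written by [exportNetwork()]
#'
#' @param path TSV or SIF file.
#' @param format `"tsv"` or `"sif"`.
#' @return data.frame of edges with unescaped ids.
#' @export
readNetwork <- function(path, format = c("tsv", "sif")) {
    format <- match.arg(format)
    if (format == "tsv") {
        e <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
        if (nrow(e)) {
            e[[1]] <- unescapeId(e[[1]])
            e[[2]] <- unescapeId(e[[2]])
        }
        e
    } else {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        parts <- strsplit(lines, " ")
        data.frame(
            from = unescapeId(vapply(parts, `[`, "", 1)),
            type = vapply(parts, `[`, "", 2),
            to = unescapeId(vapply(parts, `[`, "", 3)))
    }
}

#' Write all genome tracks of a synthetic data set
#'
#' Emits the standard-format files: `genes.gff3`, `mhs.bed`,
#' `dacrs.bed`, one BED per TF peak set, `loops.bedpe`,
#' `promoters.fasta`, `coverage.bedGraph` and `truth.json`.
#'
#' @param tracks result of [simulateGenomeTracks()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeGenomeTracks <- function(tracks, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ann <- tracks$annotation
    gff <- ann
    S4Vectors::mcols(gff) <- S4Vectors::DataFrame(
        source = "mesotraject", type = "gene", ID = ann$gene_id,
        gene_id = ann$gene_id)
    rtracklayer::export(gff, file.path(dir, "genes.gff3"),
                        format = "GFF3")
    rtracklayer::export(tracks$mhs, file.path(dir, "mhs.bed"),
                        format = "BED")
    if (length(tracks$dacrs))
        rtracklayer::export(tracks$dacrs, file.path(dir, "dacrs.bed"),
                            format = "BED")
    for (tf in names(tracks$tfPeaks))
        rtracklayer::export(tracks$tfPeaks[[tf]],
                            file.path(dir, paste0("peaks_", tf, ".bed")),
                            format = "BED")
    if (length(tracks$loops))
        writeLoops(tracks$loops, file.path(dir, "loops.bedpe"))
    Biostrings::writeXStringSet(tracks$promoters,
                                file.path(dir, "promoters.fasta"))
    rtracklayer::export(tracks$coverage,
                        file.path(dir, "coverage.bedGraph"),
                        format = "bedGraph")
    truth <- tracks$truth
    jsonlite::write_json(list(
        motifPositions = truth@motifPositions,
        loopPairs = truth@loopPairs,
        chipPairs = truth@chipPairs), file.path(dir, "truth.json"),
        digits = NA)
    invisible(dir)
}
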