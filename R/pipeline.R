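# Pipeline orchestration: configuration, staged execution, structured
# logging and a digest manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown
#' names are rejected; values are range-checked. The configuration can
#' be round-tripped through YAML with [writeConfig()]/[readConfig()].
#'
#' @param ... overrides of the defaults listed below.
#' @return a named list with class `"PipelineConfig"`.
#' @details Defaults: QC `minReads = 10000`, `maxMito = 0.2`; HVG
#' `nHvg = 1500` (capped at the gene count); embedding `nPcs = 25`,
#' `nNeighbors = 50`, `minDist = 0.1`, `embedding = "umap"`; clustering
#' resolutions 0.05 (coarse) and 0.5 (fine); dynamic genes
#' `minMean = 0.1`, `dfSpline = 3`, `qThreshold = 0.01`,
#' `kGeneClusters = 6`; coexpression `topFrac = 0.75`,
#' `edgeQuantile = 0.95`; ODE network `z = 4`, `nRuns = 50`,
#' `iters = 100`; consensus `cutoffs = c(0.1, 0.5)`; metagene
#' `flank = 1500`, `bin = 100`; network `promoterHalfwidth = 1000`,
#' `maxChain = 2`; generator sizes (`nTf = 20`, `density = 0.1`,
#' `nCells = 400`, `nTargets = 120`, `nLowq = 20`, `nGenes = 30`,
#' `chromLen = 2e5`, ...) chosen so a full synthetic run completes on a
#' laptop; `seed = 1`.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        # generator
        nTf = 20L, density = 0.1, nCells = 400L, nTargets = 120L,
        depthMean = 20000, mitoFrac = 0.05, nLowq = 20L,
        nbDispersion = 0.5,
        nGenes = 30L, chromLen = 200000L, motifFrac = 0.4,
        footprintDepth = 0.5, nLoops = 4L, nChip = 4L, nPdi = 3L,
        promWidth = 500L,
        # cells
        minReads = 10000, maxMito = 0.2, nHvg = 1500L, nPcs = 25L,
        embedding = "umap", nNeighbors = 50L, minDist = 0.1,
        resolutionCoarse = 0.05, resolutionFine = 0.5, knn = 15L,
        # trajectory
        minMean = 0.1, dfSpline = 3L, qThreshold = 0.01,
        kGeneClusters = 6L, nBins = 100L,
        # coexpr
        topFrac = 0.75, beta = 6, edgeQuantile = 0.95,
        # grn
        z = 4L, nRuns = 50L, iters = 100L, cutoffs = c(0.1, 0.5),
        # regulome
        flank = 1500L, bin = 100L, promoterHalfwidth = 1000L,
        maxChain = 2L, footprintFlank = 100L)
    dots <- list(...)
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
        stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
    stopifnot(cfg$minReads > 0, cfg$maxMito >= 0, cfg$maxMito <= 1,
              cfg$topFrac > 0, cfg$topFrac <= 1,
              cfg$density >= 0, cfg$density < 1,
              cfg$qThreshold > 0, cfg$qThreshold < 1,
              all(cfg$cutoffs >= 0))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' @describeIn pipelineConfig write a configuration as YAML.
#' @param cfg a `PipelineConfig`.
#' @param path file path.
#' @export
writeConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' @describeIn pipelineConfig read a YAML configuration (values are
#'   validated through `pipelineConfig()`).
#' @export
readConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

stageLog <- function(log, stage, ...) {
    rec <- list(stage = stage, ...)
    log[[stage]] <- rec
    log
}

#' Run the full synthetic-to-networks pipeline
#'
#' Executes the stages in order - simulate, cells (QC, HVG, embedding,
#' clustering, annotation), trajectory (pseudotime, orientation, dynamic
#' genes, profile clusters), coexpr (pseudo-bulk, TOM network), grn
#' (ODE network, consensus at both cutoffs, hubs, TF-family enrichment)
#' and regulome (metagene profile, motif scan/enrichment, footprint,
#' typed regulatory network) - writing per-stage outputs under `outdir`
#' and a manifest (`manifest.json`) with the configuration echo, the
#' per-stage record-count funnel, and an md5 digest of every output
#' file. Identical configuration and seed give a byte-identical manifest.
#'
#' Because every stage is deterministic given the configuration and
#' seed, a deleted or corrupted intermediate is resumed simply by
#' re-running: the regenerated file carries an identical digest.
#'
#' @param config a [pipelineConfig()] object.
#' @param outdir output directory.
#' @return the manifest, invisibly (a list).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cfg <- config
    log <- list()
    wtab <- function(df, name) {
        utils::write.table(df, file.path(outdir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        name
    }
    outputs <- character()

    ## simulate
    grn <- simulateGrn(cfg$nTf, cfg$density, seed = cfg$seed)
    sim <- simulateCells(grn, nCells = cfg$nCells,
                         nTargets = cfg$nTargets,
                         depthMean = cfg$depthMean,
                         mitoFrac = cfg$mitoFrac, nLowq = cfg$nLowq,
                         nbDispersion = cfg$nbDispersion,
                         seed = subSeed(cfg$seed, 1))
    tracks <- simulateGenomeTracks(
        nGenes = cfg$nGenes, chromLen = cfg$chromLen,
        motifFrac = cfg$motifFrac, footprintDepth = cfg$footprintDepth,
        nLoops = cfg$nLoops, nChip = cfg$nChip, nPdi = cfg$nPdi,
        promWidth = cfg$promWidth, seed = subSeed(cfg$seed, 2))
    writeCounts(sim$counts, file.path(outdir, "counts"))
    writeGenomeTracks(tracks, file.path(outdir, "tracks"))
    outputs <- c(outputs,
                 file.path("counts", c("matrix.mtx", "barcodes.tsv",
                                       "features.tsv")),
                 file.path("tracks",
                           list.files(file.path(outdir, "tracks"))))
    log <- stageLog(log, "simulate", seed = cfg$seed,
                    nCells = cfg$nCells,
                    nGenes = nrow(sim$counts),
                    trueEdges = nrow(grn@edges))

    ## cells
    qc <- qcFilter(sim$counts, cfg$minReads, cfg$maxMito)
    m <- qc$counts
    outputs <- c(outputs, wtab(qc$qc, "qc_report.tsv"))
    nHvg <- min(cfg$nHvg, nrow(m))
    hvg <- selectHvg(m, n = nHvg)
    emb <- embedCells(m, hvg, nPcs = min(cfg$nPcs, nHvg - 1L),
                      method = cfg$embedding,
                      nNeighbors = cfg$nNeighbors,
                      minDist = cfg$minDist, seed = subSeed(cfg$seed, 3))
    caCoarse <- clusterCells(emb, cfg$resolutionCoarse, k = cfg$knn)
    caFine <- clusterCells(emb, cfg$resolutionFine, k = cfg$knn)
    # pseudo-bulk needs enough samples: escalate the fine resolution if
    # the embedding collapses into too few communities
    resFine <- cfg$resolutionFine
    while (caFine@nClusters < 4L && resFine < 32 * cfg$resolutionFine) {
        resFine <- 2 * resFine
        caFine <- clusterCells(emb, resFine, k = cfg$knn)
    }
    if (caFine@nClusters < 4L)
        stop("fine clustering yields fewer than 4 pseudo-bulk samples")
    ancl <- annotateClusters(m, caCoarse, sim$markerPanel)
    outputs <- c(outputs,
        wtab(data.frame(cell = rownames(emb), emb,
                        clusterCoarse = clusterLabels(caCoarse),
                        clusterFine = clusterLabels(caFine)),
             "embedding.tsv"),
        wtab(ancl$dotplot, "cluster_annotation.tsv"))
    log <- stageLog(log, "cells", cellsIn = ncol(sim$counts),
                    cellsKept = ncol(m), nHvg = nHvg,
                    clustersCoarse = caCoarse@nClusters,
                    clustersFine = caFine@nClusters)

    ## trajectory
    traj <- inferPseudotime(m, genes = hvg,
                            seed = subSeed(cfg$seed, 4))
    originMarkers <- names(sim$truth@dynamicLabels)[
        sim$truth@dynamicLabels == "increasing"][1:5]
    traj <- orientTrajectory(traj, m, originMarkers)
    dyn <- testDynamicGenes(m, traj, minMean = cfg$minMean,
                            dfSpline = cfg$dfSpline,
                            qThreshold = cfg$qThreshold)
    k <- min(cfg$kGeneClusters, sum(dyn$significant))
    dyn <- clusterGeneProfiles(dyn, m, traj, k = k, nBins = cfg$nBins)
    outputs <- c(outputs,
        wtab(data.frame(cell = names(pseudotime(traj)),
                        pseudotime = pseudotime(traj),
                        state = traj@state), "pseudotime.tsv"),
        wtab(dyn, "dynamic_genes.tsv"))
    log <- stageLog(log, "trajectory", genesTested = sum(dyn$tested),
                    dynamicGenes = sum(dyn$significant),
                    geneClusters = k, rootCell = traj@rootCell)

    ## coexpr
    pb <- makePseudobulk(m, caFine, traj)
    co <- buildCoexpression(pb, topFrac = cfg$topFrac, beta = cfg$beta,
                            edgeQuantile = cfg$edgeQuantile)
    outputs <- c(outputs, wtab(networkEdges(co), "coexpr_edges.tsv"),
                 wtab(data.frame(gene = names(co@modules),
                                 module = co@modules), "modules.tsv"))
    log <- stageLog(log, "coexpr", samples = nrow(pb@expr),
                    genesKept = nrow(co@adjacency),
                    edges = nrow(networkEdges(co)))

    ## grn
    tfs <- grn@tfIds
    expr <- logNormCounts(m)[tfs, , drop = FALSE]
    ode <- fitOdeGrn(expr, pseudotime(traj), z = cfg$z,
                     nRuns = cfg$nRuns, iters = cfg$iters,
                     seed = subSeed(cfg$seed, 5))
    cons <- lapply(cfg$cutoffs, function(cu)
        consensusNetwork(ode, co, cutoff = cu))
    names(cons) <- paste0("cutoff", cfg$cutoffs)
    odeEdges <- data.frame(
        regulator = rep(tfs, each = length(tfs)),
        target = rep(tfs, length(tfs)),
        weight = as.vector(t(grnWeights(ode))))
    odeEdges <- odeEdges[odeEdges$regulator != odeEdges$target, ]
    outputs <- c(outputs, wtab(odeEdges, "ode_network.tsv"))
    for (nm in names(cons))
        outputs <- c(outputs,
                     wtab(networkEdges(cons[[nm]]),
                          paste0("consensus_", nm, ".tsv")))
    hubs <- if (nrow(networkEdges(cons[[1]])) > 0)
        hubNodes(cons[[1]], topK = 10) else NULL
    # synthetic bulk table + family map exercise the enrichment step
    fam <- stats::setNames(
        rep(c("WRKY", "ERF", "NAC", "MYB", "HSF"),
            length.out = length(tfs)), tfs)
    isBS <- sim$truth@cellType[colnames(m)] == "BS"
    bulk <- data.frame(
        gene = tfs,
        M = rowMeans(expr[, !isBS, drop = FALSE]),
        BS = rowMeans(expr[, isBS, drop = FALSE]))
    enr <- tfFamilyEnrichment(
        highExpressedTfs(bulk, "M", fam),
        highExpressedTfs(bulk, "BS", fam), fam)
    outputs <- c(outputs, wtab(enr, "tf_family_enrichment.tsv"))
    log <- stageLog(log, "grn", nTf = length(tfs),
                    nRuns = ode@nRuns,
                    consensusEdges = vapply(cons, function(cn)
                        nrow(networkEdges(cn)), integer(1)))

    ## regulome
    meta <- metageneProfile(tracks$coverage, tracks$annotation,
                            flank = cfg$flank, bin = cfg$bin)
    pwm <- hsfPwm()
    hits <- scanMotifs(pwm, tracks$promoters)
    decoys <- lapply(1:5, function(s)
        randomPwm(nrow(pwm@mat), seed = subSeed(cfg$seed, 10 + s)))
    withHit <- unique(hits$seq)
    fg <- tracks$promoters[names(tracks$promoters) %in% withHit]
    bg <- tracks$promoters[!names(tracks$promoters) %in% withHit]
    enrMotif <- if (length(fg) && length(bg))
        motifEnrichment(c(list(pwm), decoys), fg, bg) else NULL
    ghits <- motifHitsToGenome(hits, tracks$annotation,
                               motifWidth = nrow(pwm@mat),
                               promWidth = cfg$promWidth)
    fp <- aggregateFootprint(tracks$coverage, ghits,
                             w = cfg$footprintFlank)
    regnet <- buildRegulatoryNetwork(
        tracks$annotation, tracks$tfPeaks, tracks$mhs, tracks$dacrs,
        tracks$loops, consensus = cons[[1]],
        promoterHalfwidth = cfg$promoterHalfwidth,
        maxChain = cfg$maxChain)
    outputs <- c(outputs,
        wtab(data.frame(group = rownames(meta@profile), meta@profile),
             "metagene_profile.tsv"),
        wtab(hits, "motif_hits.tsv"),
        wtab(data.frame(position = seq_along(fp@profile),
                        coverage = fp@profile), "footprint.tsv"))
    if (!is.null(enrMotif))
        outputs <- c(outputs, wtab(enrMotif, "motif_enrichment.tsv"))
    exportNetwork(regnet, file.path(outdir, "regnet.tsv"), "tsv")
    exportNetwork(regnet, file.path(outdir, "regnet.sif"), "sif")
    outputs <- c(outputs, "regnet.tsv", "regnet.sif")
    etab <- table(networkEdges(regnet)$type)
    log <- stageLog(log, "regulome", motifHits = nrow(hits),
                    footprintSites = fp@nSites,
                    edges = stats::setNames(as.integer(etab),
                                            names(etab)))

    ## manifest
    digests <- tools::md5sum(file.path(outdir, outputs))
    names(digests) <- outputs
    manifest <- list(
        version = as.character(utils::packageVersion("mesotraject")),
        config = unclass(cfg),
        stages = log,
        digests = as.list(digests))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
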