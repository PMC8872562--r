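test_that("qcFilter applies strict thresholds and is idempotent", {
    cts <- matrix(0L, 3, 4,
                  dimnames = list(c("g1", "g2", "mitoA"),
                                  paste0("c", 1:4)))
    cts["g1", ] <- c(9999L, 10000L, 20000L, 16000L)
    cts["mitoA", ] <- c(0L, 0L, 0L, 4000L)   # c4: ratio 0.2 exactly
    m <- MesoCounts(cts)
    res <- qcFilter(m)
    # 9,999 reads removed; exactly 10,000 retained; ratio 0.2 retained
    expect_identical(res$qc$pass, c(FALSE, TRUE, TRUE, TRUE))
    expect_identical(res$qc$reason[1], "reads")
    expect_identical(colnames(res$counts), paste0("c", 2:4))
    expect_identical(rownames(res$counts), rownames(m))

    cts2 <- cts
    cts2["mitoA", 3] <- 6000L  # ratio 6000/26000 > 0.2
    res2 <- qcFilter(MesoCounts(cts2))
    expect_identical(res2$qc$reason[3], "mito")
    expect_false(res2$qc$pass[3])

    # idempotence: filtering a filtered matrix removes nothing
    res3 <- qcFilter(res$counts)
    expect_identical(colnames(res3$counts), colnames(res$counts))

    # all-fail carries counts per reason
    bad <- MesoCounts(matrix(c(1L, 1L), 2, 1,
                             dimnames = list(c("g1", "mitoA"), "c1")))
    expect_error(qcFilter(bad), "reads: 1")
})

test_that("HVG selection ranks by standardized dispersion with stable ties", {
    set.seed(1)
    n <- 60
    cts <- matrix(rpois(100 * n, 5), 100, n,
                  dimnames = list(sprintf("g%03d", 1:100),
                                  sprintf("c%02d", 1:n)))
    expect_length(selectHvg(mkCounts(cts), 30), 30L)
    expect_error(selectHvg(mkCounts(cts), 101), "exceeds")

    # identical counts for all genes: ties broken lexicographically
    flat <- matrix(rep(c(0L, 3L, 1L, 5L), times = 10), 10, 4,
                   byrow = TRUE,
                   dimnames = list(sprintf("t%02d", c(3, 1, 2, 10, 4:9)),
                                   paste0("c", 1:4)))
    got <- selectHvg(mkCounts(flat), 3)
    expect_identical(got, sort(rownames(flat))[1:3])

    # two-gene toy: the gene with higher variance/mean ranks first
    toy <- rbind(a_low = rep(c(4L, 5L), 10),
                 b_high = rep(c(0L, 9L), 10))
    colnames(toy) <- paste0("c", 1:20)
    expect_identical(selectHvg(mkCounts(toy), 1), "b_high")
})

test_that("embedding has one 2-D coordinate per cell and is deterministic", {
    set.seed(2)
    cts <- matrix(rpois(50 * 80, 6), 50, 80,
                  dimnames = list(sprintf("g%02d", 1:50),
                                  sprintf("c%02d", 1:80)))
    m <- mkCounts(cts)
    hvg <- selectHvg(m, 30)
    emb <- embedCells(m, hvg, nPcs = 10, method = "pca", seed = 1)
    expect_identical(dim(emb), c(80L, 2L))
    expect_identical(rownames(emb), colnames(cts))
    expect_error(embedCells(m, hvg, nPcs = 60, method = "pca"), "nPcs")
    expect_error(embedCells(m, character(0)), "non-empty")

    # duplicated cells land on identical coordinates
    cts2 <- cbind(cts, dup1 = cts[, 1], dup2 = cts[, 1])
    m2 <- mkCounts(cts2)
    emb2 <- embedCells(m2, hvg, nPcs = 10, method = "pca", seed = 1)
    expect_equal(emb2["dup1", ], emb2["c01", ])
    expect_equal(emb2["dup2", ], emb2["c01", ])
})

test_that("planted blobs separate in the embedding (positive silhouette)", {
    set.seed(3)
    # two expression programs: 40 cells each, disjoint active gene sets
    mu <- matrix(1, 40, 80)
    mu[1:20, 1:40] <- 25
    mu[21:40, 41:80] <- 25
    cts <- matrix(rpois(length(mu), mu), 40, 80,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("c%02d", 1:80)))
    m <- mkCounts(cts)
    emb <- embedCells(m, rownames(cts), nPcs = 10, method = "pca",
                      seed = 1)
    lab <- rep(1:2, each = 40)
    d <- as.matrix(dist(emb))
    sil <- vapply(seq_len(80), function(i) {
        a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
        b <- mean(d[i, lab != lab[i]])
        (b - a) / max(a, b)
    }, numeric(1))
    expect_gt(mean(sil), 0)
})

test_that("Louvain clustering recovers planted blobs and relabels contiguously", {
    blobs <- mkBlobs(k = 8, per = 40, seed = 4)
    ca <- clusterCells(blobs$embedding, resolution = 0.05)
    expect_s4_class(ca, "ClusterAssignment")
    expect_equal(ca@nClusters, 8L)
    expect_equal(adjustedRand(clusterLabels(ca), blobs$membership), 1)
    expect_identical(sort(unique(clusterLabels(ca))), 0:7)

    # two disconnected components (well-separated pairs of blobs)
    b2 <- mkBlobs(k = 2, per = 30, sep = 100, seed = 5)
    ca2 <- clusterCells(b2$embedding, resolution = 0.05)
    expect_equal(ca2@nClusters, 2L)

    # degenerate all-identical coordinates: single cluster with warning
    same <- matrix(1, 20, 2,
                   dimnames = list(paste0("c", 1:20), NULL))
    expect_warning(ca3 <- clusterCells(same, 0.5), "degenerate")
    expect_equal(ca3@nClusters, 1L)
})

test_that("cluster count is non-decreasing along a resolution grid", {
    blobs <- mkBlobs(k = 6, per = 30, seed = 6)
    grid <- c(0.05, 0.3, 0.5, 1, 2)
    ks <- vapply(grid, function(r)
        clusterCells(blobs$embedding, r)@nClusters, integer(1))
    expect_true(all(diff(ks) >= 0))
})

test_that("marker annotation computes dot-plot statistics exactly", {
    g <- simulateGrn(5, density = 0.2, seed = 7)
    sim <- simulateCells(g, nCells = 250, nLowq = 0, seed = 7)
    m <- sim$counts
    emb <- embedCells(m, selectHvg(m, 100), nPcs = 20, method = "pca",
                      seed = 1)
    ca <- clusterCells(emb, resolution = 0.05)
    ann <- annotateClusters(m, ca, sim$markerPanel)

    # oracle recomputation of one dot-plot cell
    e <- logNormCounts(m)
    lab <- clusterLabels(ca)[colnames(m)]
    row <- ann$dotplot[ann$dotplot$cluster == 0 &
                       ann$dotplot$gene == "markM01", ]
    cells0 <- names(lab)[lab == 0]
    expect_equal(row$meanExpr, mean(e["markM01", cells0]))
    cts <- as.matrix(SummarizedExperiment::assay(m, "counts"))
    expect_equal(row$fracExpressing, mean(cts["markM01", cells0] > 0))

    # a marker expressed in every cell of a cluster has fraction 1
    allOn <- rownames(cts)[rowSums(cts == 0) == 0][1]
    panel2 <- data.frame(gene = allOn, cellType = "X", direction = "up")
    ann2 <- annotateClusters(m, ca, rbind(sim$markerPanel, panel2))
    expect_true(all(ann2$dotplot$fracExpressing[
        ann2$dotplot$gene == allOn] == 1))

    # the BS-minority population, taken as its own cluster, is labeled
    # BS by the panel vote
    isBS <- sim$truth@cellType[colnames(m)] == "BS"
    caT <- methods::new("ClusterAssignment",
                        labels = stats::setNames(as.integer(isBS),
                                                 colnames(m)),
                        resolution = 0.05, nClusters = 2L)
    annT <- annotateClusters(m, caT, sim$markerPanel)
    expect_identical(unname(annT$assignment["1"]), "BS")
    expect_identical(unname(annT$assignment["0"]), "M")

    # permuting the cell order changes no statistic
    perm <- sample(ncol(m))
    mP <- m[, perm]
    caP <- methods::new("ClusterAssignment",
                        labels = clusterLabels(ca)[colnames(mP)],
                        resolution = ca@resolution,
                        nClusters = ca@nClusters)
    annP <- annotateClusters(mP, caP, sim$markerPanel)
    expect_equal(annP$dotplot[order(annP$dotplot$cluster,
                                    annP$dotplot$gene), ],
                 ann$dotplot[order(ann$dotplot$cluster,
                                   ann$dotplot$gene), ],
                 ignore_attr = TRUE)

    # absent markers are reported, not fatal
    panel3 <- rbind(sim$markerPanel,
                    data.frame(gene = "nope", cellType = "M",
                               direction = "up"))
    expect_identical(annotateClusters(m, ca, panel3)$missing, "nope")
})
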