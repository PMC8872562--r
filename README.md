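# mesotraject

Stage-specific transcription-factor regulatory networks from
single-cell trajectories in the maize mesophyll.

## The problem

Maize mesophyll (M) cells mature along the leaf's base-to-tip axis, and
the transcription factors (TFs) that drive that maturation change with
developmental stage. `mesotraject` is an R/Bioconductor-style toolkit
that reconstructs those stage-specific TF networks from droplet
scRNA-seq of M cells, integrating bulk expression, MNase
hypersensitivity (MHS), TF ChIP peaks and H3K4me3 HiChIP chromatin
loops. It is aimed at plant genomicists who have a 10x-style UMI matrix
plus standard genomic tracks (BED/bedGraph/BEDPE/GFF3/FASTA) and want
to go from counts to typed regulatory edges in one scriptable pipeline.

## The models at the core

* **Pseudotime.** Cells are embedded (log1p CP10K, PCA), k-means
  centroids are joined by a minimum spanning tree, cells are projected
  onto the tree, and pseudotime is geodesic distance from the root,
  min-max normalized to [0, 1]. The root is chosen so a marker panel
  known to be lowest at the leaf base (AspAT, NADP-MDH, PPDK, CA, PEPC
  in real data) is minimal at pseudotime 0.
* **Dynamic genes.** For each expressed gene (mean normalized count
  > 0.1), a negative-binomial GLM with a natural cubic spline of
  pseudotime (df = 3) is tested against an intercept-only null by a
  likelihood-ratio chi-squared test; q-values by Benjamini-Hochberg.
  Significant genes are binned over 100 pseudotime bins, z-scored and
  Ward-clustered into profile clusters G1..G6 ordered by peak time.
* **Coexpression.** Cells are pooled by fine Louvain clusters into
  pseudo-bulk samples (log2(RPM+1), sample pseudotime = mean member
  pseudotime). On the top-75%-dispersed genes, the unsigned weighted
  network is a_ij = |cor(x_i, x_j)|^beta and the topological overlap is

      TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)

  with connections defined above a TOM quantile.
* **Linear-ODE network.** TF expression over pseudotime t is fit as
  x(t) ~ W exp(b t) with latent dimension z = 4; latent rates b are
  optimized by iterative random replacement and W by least squares;
  each run yields A = W diag(b) W+ (so dx/dt ~ A x) and the reported
  network is the element-wise mean of 50 runs. Consensus networks keep
  edges with |A| above a cutoff (presets 0.1 and 0.5) that are also
  coexpression connections; hubs are ranked by degree.
* **Enrichment and regulome.** TF-family enrichment compares observed
  highly expressed TF counts to expected = |high| x n_family / N by a
  chi-squared test (df = 1). Metagene profiles average normalized
  coverage in 100-bp bins over TSS +/- 1.5 kb. PWMs are scanned by
  log-odds on both strands; enrichment between sequence sets uses
  one-sided Fisher tests; footprints average coverage around aligned
  motif hits. Typed regulatory edges are built from evidence:
  `chip_direct` (TF peak in the +/- 1 kb promoter), `PPI` (promoters
  joined by chains of anchor-overlapping loops), `PDI` (TF peak on a
  distal accessible region looped to a promoter) and `predicted`
  (consensus network), each with re-validatable provenance.

A synthetic-data module (`simulateGrn`, `simulateCells`,
`simulateGenomeTracks`) generates every input with recorded ground
truth — latent cell times, a true signed TF network, planted
low-quality cells, motif instances, footprints, peaks and loops — so
every stage is testable without downloads.

## Worked example

```r
library(mesotraject)

grn <- simulateGrn(20, density = 0.1, seed = 1)
sim <- simulateCells(grn, nCells = 500, nLowq = 25, seed = 7)

qc <- qcFilter(sim$counts)              # reads >= 10,000, mito <= 0.2
ncol(qc$counts)
#> [1] 475

m   <- qc$counts
tr  <- inferPseudotime(m, selectHvg(m, 150), seed = 1)
inc <- names(sim$truth@dynamicLabels)[
    sim$truth@dynamicLabels == "increasing"][1:5]
tr  <- orientTrajectory(tr, m, inc)
cor(pseudotime(tr), sim$truth@trueTime[names(pseudotime(tr))],
    method = "spearman")
#> [1] 0.9943612

dyn <- testDynamicGenes(m, tr)          # NB spline LRT per gene
sum(dyn$significant)
#> [1] 188
dyn <- clusterGeneProfiles(dyn, m, tr, k = 6)
table(dyn$cluster[dyn$significant])     # G1..G6 ordered by peak time
#>  G1  G2  G3  G4  G5  G6
#>  36  29   9  53   9  52
```

The 475 retained cells are exactly the 475 non-planted ones; the
Spearman correlation of 0.994 says the inferred ordering recovers the
generator's latent time almost perfectly; the 188 significant genes are
the planted dynamic templates plus the ODE-driven TFs.

The full pipeline (simulation → QC/clustering → pseudotime → dynamic
genes → pseudo-bulk coexpression → ODE network → consensus → motifs,
footprints and loop edges) runs with:

```r
man <- runPipeline(pipelineConfig(seed = 1), "out/")
```

writing per-stage TSV/BED/BEDPE/FASTA/bedGraph outputs plus
`manifest.json` with the record-count funnel and an md5 digest of every
file; identical configuration and seed reproduce the manifest
byte-for-byte.

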