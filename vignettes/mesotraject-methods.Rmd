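---
title: "From single-cell trajectories to stage-specific TF networks: models and design"
author: "mesotraject authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-cell trajectories to stage-specific TF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesotraject)
```

# Overview

`mesotraject` reconstructs developmental-stage-specific
transcription-factor (TF) regulatory networks for maize mesophyll (M)
cells from droplet scRNA-seq, with epigenomic integration. This
vignette is the package's account of the science: the models at each
stage, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator emulates (and
deliberately does not), the numerical choices, and the known
limitations — including one identifiability limit of the network
inference that users should understand before interpreting edge
weights.

# Quality control and cell processing

A cell passes QC when its total read count is at least 10,000 and its
mitochondrial read fraction is at most 0.2. Both thresholds are strict
on the failure side ("fewer than 10,000" and "higher than 0.2" fail),
so a cell sitting exactly on a threshold is retained. The thresholds
are the standard ones for maize leaf protoplast scRNA-seq at roughly
45,000 reads per cell; for shallower libraries the `minReads` argument
should be lowered accordingly.

Highly variable genes are ranked by the classic mean-binned dispersion:
genes are placed into 20 equal-frequency bins of mean log-normalized
expression, dispersion is `log(variance/mean)`, and dispersions are
z-scored within bins. The binning removes the mean-dispersion trend so
that highly expressed housekeeping genes do not crowd out genuinely
variable ones. Ties are broken by lexicographic gene id, making the
ranking deterministic. The conventional `n = 1500` top genes feed a
25-component PCA.

Two-dimensional embedding is pluggable: UMAP (`n_neighbors = 50`,
`min_dist = 0.1`, via the uwot package when installed) or the first two
principal components (`method = "pca"`). UMAP is the better
visualization; PCA-2D is exact, fast and used throughout the test suite
because its determinism does not depend on a third-party
implementation. Clustering is Louvain community detection on a
k-nearest-neighbor graph (`k = 15`) built from the 2-D coordinates,
with resolution presets 0.05 (coarse cell types) and 0.5 (fine clusters
that become pseudo-bulk samples). Clustering on the 2-D embedding
rather than the PC space mirrors the workflow this package
reimplements; `k = 15` is the common default for graphs of a few
thousand cells. Labels are always relabeled to `0..k-1` by decreasing
cluster size.

Marker-based annotation computes, per cluster and marker, the mean
log-normalized expression and the fraction of cells with a non-zero
count (the two numbers a dot plot shows), standardizes each marker's
cluster means across clusters, and assigns each cluster the cell type
whose markers score highest on average. Permuting cells changes no
statistic.

# Pseudotime

The trajectory model is a cluster-centroid minimum spanning tree:
cells are embedded (log1p CP10K, gene-scaled, PCA to 2 components),
k-means finds `max(4, min(30, sqrt(n)))` centroids, a Euclidean MST
joins them, each cell is projected onto its nearest tree edge, and
pseudotime is the geodesic distance from a provisional root (one end of
the tree diameter), min-max normalized to [0, 1]. This keeps the
contract of tree-based trajectory tools — a spanning tree in a
2-component reduction with cells ordered along it — while remaining
fully deterministic given the seed and simple enough to verify against
ground truth. A projection-based pseudotime is piecewise-linear along
the tree, which is adequate for the single dominant path these data
have; it is not a multi-branch fate model.

Orientation is decided by origin markers: among the two directions, the
one minimizing mean marker expression in the lowest-pseudotime decile
of cells is chosen. This encodes the biological rooting rule for
maturation gradients (C4 photosynthesis genes are lowest at the leaf
base). If the two ends differ by less than a tolerance the orientation
is reported as ambiguous rather than guessed; trajectories with more
than two ends likewise require the marker panel to disambiguate.
Reversal is exact: `p -> 1 - p`.

# Pseudotime-dynamic genes

Genes with mean size-factor-normalized expression above 0.1 are tested
with a negative-binomial GLM: a natural cubic spline of pseudotime with
3 degrees of freedom (plus a log library-size offset) against an
intercept-only null, compared by a likelihood-ratio chi-squared test on
3 degrees of freedom. The NB size parameter is estimated per gene under
the null and shared by both models — a deliberate choice that makes the
null calibrated (estimating the dispersion under the alternative would
let strong trends masquerade as low dispersion) at the cost of slight
conservatism for very strong effects. Benjamini-Hochberg adjustment is
applied across tested genes; fit failures are flagged and excluded. The
significance default is `q < 0.01`; it is a config value because the
number of "dynamic" genes is threshold-sensitive.

On pure-null NB panels (1,000 genes, 500 cells) the realized fraction
with `q < 0.05` stays below 0.01, and 2-fold monotone effects are
detected with power above 0.9 — both recomputed by the test suite and
the acceptance script at those sizes.

Profile clustering bins cells into 100 equal-width pseudotime bins,
averages log1p normalized expression per bin (empty bins filled by
linear interpolation), z-scores each gene, and cuts a Ward tree into
`k = 6` clusters labeled G1..G6 in order of their mean-profile peak
time, so G1 always peaks earliest (base-like) and the last cluster
peaks latest (tip-like). Binned means rather than a smoother keep the
profiles exactly recomputable by hand.

# Pseudo-bulk coexpression

Cells are pooled by fine cluster; each sample's counts are scaled to
reads per million (rows sum to 1e6) and log2(RPM + 1) transformed; each
sample carries the mean pseudotime of its member cells. With on the
order of 22 samples, per-pair correlation tests would be underpowered
and are not used; instead the unsigned weighted-network convention
applies: adjacency `|cor|^beta` (Pearson), topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \neq i} a_{iu},$$

and "connections" defined as pairs above the 0.95 quantile of
off-diagonal TOM values. Dispersion for the top-75% gene filter is
computed on the pseudo-bulk matrix (the object being analyzed), not on
cells. The soft power can be chosen automatically (smallest power in
1..20 reaching scale-free fit R² ≥ 0.8, falling back to 6 with a
warning) or fixed; the pipeline default is 6, the unsigned-network
convention. The TOM implementation is matrix-algebra; the test suite
checks it to 1e-10 against an independent triple-loop oracle, and the
two-gene perfectly-correlated case is the exact fixed point
adjacency = TOM = 1.

# Linear-ODE network inference

TF expression over pseudotime is modeled as a latent linear ODE:
`dz/dt = diag(b) z` with `z` of dimension 4, observed through
`x(t) = W z(t)`, so that `A = W diag(b) W⁺` satisfies `dx/dt = A x`.
Fitting follows the random-restart scheme: `b` is drawn uniformly from
[-10, 2], refined for 100 iterations by resampling one coordinate at a
time and keeping improvements in the least-squares residual of
`x ≈ W exp(b t)` (W refit each step), and the per-run `A` matrices of
50 restarts are averaged element-wise. Averaging is what makes the
edge weights usable: across repetitions, 50-run averages show roughly
20-fold lower variance than single runs (the acceptance script reports
the measured ratio). Input expression should be log-scale; the
`center = TRUE` default removes each TF's baseline so the latent model
acts on deviations, which is where the linear approximation is
meaningful. Pseudotime must already be normalized to [0, 1]; values
outside are an error, not silently rescaled.

**Identifiability limit.** `A = W diag(b) W⁺` has rank at most `z = 4`.
When the true network is a sparse random full-rank matrix — as the
synthetic generator plants — the best this estimator can return is the
projection of the truth onto the 4 temporal modes the data expose.
Numerically, even on noiseless latent trajectories and with the true
eigenvalues supplied to the fit, edge-ranking AUROC against such a
truth plateaus around 0.65-0.70 (and lower once counting noise is
added); this is a property of the model class, not of the optimizer,
run count or data volume. Interpretation: on real data the averaged
weights rank regulator-target candidates and identify hubs; they are
not a consistent estimator of individual edges, which is precisely why
the workflow intersects them with the coexpression network and with
physical evidence (peaks and loops) before calling an edge. The
generator deliberately keeps planting full-rank sparse truths — biology
is not rank-4 — and its self-degradation rates default to
[0.2, 0.5] x `weightScale`, slower than the coupling magnitudes
([0.5, 1.5]), so that regulation rather than uniform decay dominates
the observable dynamics; this is the regime in which recovery metrics
are informative at all.

Consensus networks keep directed pairs with `|A|` at or above a cutoff
(presets 0.1 exploratory, 0.5 condensed) **and** coexpression support.
The absolute value is used so repressive edges survive; the cutoff
applies to the averaged weight (the per-run-frequency alternative is
noted but not used). Hubs are ranked by degree over unique undirected
partners, ties broken by summed |weight| then id.

TF-family enrichment uses the expected-count rule: for a family with
`n_f` of `N` total TFs, the expected number among `H` highly expressed
TFs is `H * n_f / N`, compared by a 2-category chi-squared test
(df = 1); the expectations sum to `H` by construction. When an
expectation is zero, an exact binomial test substitutes and the family
is flagged. "Highly expressed" lists are caller-provided; the helper
`highExpressedTfs()` derives them as the top quartile per cell type of
a bulk table, since no sharper definition exists.

# Regulome integration

Metagene profiles average coverage, normalized to counts per million of
the track total, in 100-bp bins across [TSS - 1.5 kb, TSS + 1.5 kb)
(30 bins); minus-strand windows are reversed so bins always run 5' to
3'. Genes whose window leaves the chromosome are skipped and listed.

Motifs are width-by-4 probability matrices; scanning is log-odds
against the background on both strands, with non-ACGT letters scoring
zero (background). The default threshold is 80% of the maximum
achievable score — permissive enough to keep one-off degenerate
positions, strict enough that random 500-bp sequences rarely hit. The
HSF consensus AGAAnnTTCT is built in (`hsfPwm()`); its two degenerate
center positions carry uniform columns. Note the consensus is
palindromic, so every hit is reported on both strands. Enrichment
between a foreground and a background sequence set is a per-motif
one-sided Fisher exact test on sequences-with-hits, BH-corrected across
motifs. Footprints average per-base coverage in a +/- 100 bp window
around aligned hits (minus-strand hits reversed); a bound factor shows
as a dip over the motif span.

Typed network edges and their evidence:

* `chip_direct` — a TF ChIP peak overlaps the target's promoter window,
  TSS +/- 1 kb. The 1 kb half-width follows the proximal-MHS usage for
  network membership; footprint-to-gene association, which uses a
  tighter 500 bp in the literature, takes its own parameter instead of
  inheriting this one.
* `PPI` — both promoters lie on loop anchors connected by a chain of at
  most `maxChain = 2` loops whose anchors overlap. "Consecutive loops"
  is not defined more precisely anywhere we know of; anchor-overlap
  chaining with chain length 2 (A-B plus B-C) is the minimal reading
  and is exposed in config.
* `PDI` — a TF peak overlaps a distal accessible chromatin region
  (dACR) that is loop-anchored to the gene's promoter. Overlap means
  >= 1 bp throughout; no fraction threshold is imposed.
* `predicted` — imported from the consensus network.

Every edge records provenance (peak, dACR and loop identifiers, or the
consensus weight) and `validateProvenance()` re-checks each edge's rule
from its record; the test suite asserts this closes on planted
configurations. Coordinates follow the field's conventions: BED and
bedGraph are 0-based half-open on disk, GFF3 1-based closed, GRanges
1-based closed in memory; the TSS of a minus-strand gene is its end
coordinate.

# The synthetic-data generator

The generator emulates the statistical structure of the study system so
that every stage has a computable ground truth.

* `simulateGrn()` draws a signed TF x TF matrix: off-diagonal entries
  non-zero with probability `density` (default 0.1), magnitudes uniform
  [0.5, 1.5], random sign; self-degradation (diagonal) uniform
  -[0.2, 0.5]. See the identifiability note above for why degradation
  is slower than coupling.
* `simulateCells()` gives each cell a latent time uniform on [0, 1].
  TF log-expression follows the linear ODE (solved in closed form via
  the eigendecomposition; an alternative `mode = "logistic"` swaps in
  sigmoid templates to probe robustness to model misspecification).
  Target genes follow increasing / decreasing / transient templates
  with a log-scale amplitude of log(2.5) (>2-fold swing); flat and
  marker genes complete the panel, with additive marker offsets
  defining a 90/10 M-like/BS-like mixture. Counts are sampled by a
  Dirichlet-multinomial: the Dirichlet layer (concentration
  `nGenes / nbDispersion`) supplies negative-binomial-like per-gene
  overdispersion while the multinomial layer makes each cell's total
  exactly its sampled library size, so read-count conservation is an
  exact invariant rather than an approximation. Library sizes are
  log-normal around `depthMean = 20000` (CV 0.25), floored at 60% of
  the mean so that only planted cells can fail the read-count QC
  threshold — planted low-quality cells get either 3,000-8,000 reads
  or a 35% mitochondrial fraction, and the planted set is therefore
  provably the exact QC-failure set. The deposited data's per-cell
  depth distribution beyond its mean is unknown; these defaults are
  chosen as realistic, not calibrated.
* `simulateGenomeTracks()` lays out genes with alternating strand on a
  toy chromosome, builds a random sequence, plants consensus motif
  instances (degenerate positions sampled) at recorded offsets in a
  subset of promoters, raises coverage over promoter MHS peaks and
  depletes it by `footprintDepth` across each planted motif, and
  plants TF ChIP peaks, dACRs and loops realizing known chip/PPI/PDI
  pairs — including one two-loop chain — on disjoint gene sets, so the
  recorded truth is exhaustive and network reconstruction can be
  checked for set equality, not just recall.

What the generator does **not** emulate, and hence what green tests do
not certify on real data: ambient RNA and doublets, batch effects,
gene-length and GC biases, genuine branch points in the trajectory,
nonlinear regulatory kinetics (beyond the logistic mode), motif
co-occurrence structure, and realistic loop-anchor size distributions.

# Pipeline, determinism and problem sizes

`runPipeline()` executes simulate → cells → trajectory → coexpr → grn →
regulome, writing standard-format outputs and `manifest.json` with a
configuration echo, per-stage record counts (the funnel: cells in,
cells kept, genes tested, edges kept is reconstructible from the
manifest alone) and an md5 digest per file. All randomness derives from
one seed through fixed substreams, so identical configuration plus seed
gives byte-identical manifests; a deleted intermediate is "resumed" by
re-running, which reproduces its digest. If the fine clustering
collapses below 4 communities (possible on small simulations), the
resolution is doubled until pseudo-bulk has enough samples.

Default simulation sizes (400-500 cells, ~200 genes, 20 TFs, 30
genomic genes on a 200 kb toy chromosome, 50 ODE restarts) were chosen
so that a complete run takes well under a minute on a single core while
every statistical property under test (QC exactness, ordering recovery,
test calibration and power, purity, AUROC, determinism) is measured at
a sample size where it is stable; the acceptance script states the `n`
it used alongside every value.

# Known limitations

* Single dominant trajectory path; branch-rich tissues need a fate
  model, not this package.
* The ODE network's rank-4 structure bounds edge-level recovery (see
  above); treat weights as rankings, and consensus/physical edges as
  the callable set.
* With ~22 pseudo-bulk samples the coexpression network has no
  edge-level error control; the TOM quantile is a screening threshold.
* The NB spline test assumes cells are independent along pseudotime;
  trajectories with strong batch-by-time confounding will inflate it.
* Motif scanning is PWM-based; no higher-order sequence model.
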