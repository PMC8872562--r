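Package: mesotraject
Title: Stage-Specific Transcription-Factor Regulatory Networks from
    Single-Cell Trajectories in the Maize Mesophyll
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for reconstructing
    developmental-stage-specific transcription-factor regulatory networks
    from droplet single-cell RNA-seq of maize mesophyll cells. Provides
    quality control and Louvain clustering of UMI count matrices,
    minimum-spanning-tree pseudotime with marker-based orientation,
    negative-binomial spline tests for pseudotime-dynamic genes,
    pseudo-bulk weighted coexpression (adjacency and topological overlap)
    networks, linear-ODE regulatory-network inference with run averaging,
    consensus filtering, chi-squared transcription-factor family
    enrichment, TSS metagene profiles, PWM motif scanning and enrichment
    within MNase-hypersensitive sites, nuclease footprint aggregation,
    and chromatin-loop-based promoter-promoter and promoter-distal edge
    construction. A synthetic-data module with full ground truth (latent
    trajectory, true network, planted motifs, peaks and loops) makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    MASS,
    splines,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    SingleCellExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    uwot,
    deSolve,
    optparse
biocViews: SingleCell, Transcriptomics, NetworkInference, Epigenetics,
    GeneRegulation, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
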