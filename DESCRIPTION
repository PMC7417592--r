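Package: ascfate
Title: Branching Differentiation Analysis of Activated B Cells into
    Antibody-Secreting Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for resolving LPS-activated B cells into an
    antibody-secreting-cell (ASC) destined branch and a non-ASC branch from
    single-cell and division-sorted bulk RNA-seq profiles. Implements ERCC
    spike-in absolute quantification (mRNA molecules per cell) of bulk
    profiles, detection filtering and BH-FDR differential-expression
    flagging, single-cell QC and normalization, Markov diffusion imputation,
    quantile-normalized k-nearest-neighbor annotation of single cells
    against bulk reference panels, density-peak clustering with a minimum
    spanning tree pseudotime and branch-point detection, preranked gene-set
    enrichment with a permutation null and leading-edge extraction, and
    regulon (transcription-factor target set) activity scoring. Ships a
    division-structured synthetic data generator with ground truth so every
    stage is exercisable and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
biocViews: SingleCell, Transcriptomics, GeneExpression, Normalization,
    Clustering, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
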