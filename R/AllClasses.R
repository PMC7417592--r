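#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Simulation configuration
#'
#' Parameters of the division-structured B-cell differentiation simulator.
#' Defaults encode the experimental design the analysis assumes: activated B
#' cells traverse up to eight divisions with multiplicatively growing total
#' mRNA content, bifurcate after the branch-point division into an
#' ASC-destined and a non-ASC lineage, and terminal ASC split further into an
#' ER-stress sub-state. A constant pool of spike-in transcripts is added to
#' every cell so that absolute quantification is recoverable.
#'
#' @slot nCells number of cells to simulate.
#' @slot nGenes number of biological genes.
#' @slot nSpikes number of spike-in species (ERCC analogs).
#' @slot divisions integer vector of division indices cells may occupy.
#' @slot branchDivision division at which the two lineages split.
#' @slot ascFraction probability that a cell is a terminal ASC
#'   (division 8, ASC-destined branch).
#' @slot erStressFraction proportion of terminal ASC in the ER-stress
#'   sub-state.
#' @slot branchBias probability that a non-terminal post-branch cell lies on
#'   the ASC-destined branch.
#' @slot mrnaScalePerDivision multiplicative total-mRNA growth per division
#'   (>= 1).
#' @slot moduleSizes named integer vector of marker-module gene counts
#'   (asc, bcell, oxphos, inflam, erstress, activation).
#' @slot nbDispersion negative-binomial dispersion of UMI counts.
#' @slot libsizeCV coefficient of variation of the per-cell capture
#'   efficiency (lognormal, applied equally to genes and spikes).
#' @slot programWalkSd per-gene log-scale sd of the division-to-division
#'   random walk that makes successive division states transcriptomically
#'   distinct (progressive reprogramming); 0 gives smoothly interpolating
#'   programs.
#' @slot baseLibSize expected biological UMI per cell at division 0.
#' @slot spikePoolSize expected total spike-in UMI per cell (division
#'   independent).
#' @slot bulkReplicates replicates per reference-panel label.
#' @slot bulkNoiseSd lognormal sd of multiplicative replicate noise in the
#'   bulk reference panel (0 = noise free).
#' @slot seed integer seed; fixed seed gives byte-identical output.
#'
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig", representation(
    nCells = "integer",
    nGenes = "integer",
    nSpikes = "integer",
    divisions = "integer",
    branchDivision = "integer",
    ascFraction = "numeric",
    erStressFraction = "numeric",
    branchBias = "numeric",
    mrnaScalePerDivision = "numeric",
    moduleSizes = "integer",
    nbDispersion = "numeric",
    libsizeCV = "numeric",
    programWalkSd = "numeric",
    baseLibSize = "numeric",
    spikePoolSize = "numeric",
    bulkReplicates = "integer",
    bulkNoiseSd = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nCells < 0L || object@nGenes < 0L || object@nSpikes < 0L)
        msg <- c(msg, "nCells, nGenes and nSpikes must be non-negative")
    if (object@ascFraction < 0 || object@ascFraction > 1)
        msg <- c(msg, "ascFraction must lie in [0, 1]")
    if (object@erStressFraction < 0 || object@erStressFraction > 1)
        msg <- c(msg, "erStressFraction must lie in [0, 1]")
    if (object@branchBias < 0 || object@branchBias > 1)
        msg <- c(msg, "branchBias must lie in [0, 1]")
    if (object@mrnaScalePerDivision < 1)
        msg <- c(msg, "mrnaScalePerDivision must be >= 1")
    if (any(object@moduleSizes < 0L))
        msg <- c(msg, "moduleSizes must be non-negative")
    if (sum(object@moduleSizes) > object@nGenes)
        msg <- c(msg, "sum(moduleSizes) must not exceed nGenes")
    if (length(object@divisions) == 0L || any(object@divisions < 0L))
        msg <- c(msg, "divisions must be a non-empty set of non-negative integers")
    if (!(object@branchDivision %in% object@divisions))
        msg <- c(msg, "branchDivision must be one of the simulated divisions")
    if (object@bulkReplicates < 1L)
        msg <- c(msg, "bulkReplicates must be >= 1")
    if (object@nbDispersion < 0 || object@libsizeCV < 0 ||
        object@bulkNoiseSd < 0 || object@programWalkSd < 0)
        msg <- c(msg, "dispersion and noise parameters must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Markov diffusion operator over cells
#'
#' Row-stochastic cell-by-cell transition matrix built from an adaptive
#' Gaussian kernel on the k-nearest-neighbor graph in principal-component
#' space. Powers of the operator smooth (impute) expression profiles by
#' sharing information across transcriptomic neighbors.
#'
#' @slot transitions row-stochastic numeric matrix (cells x cells).
#' @slot k neighbors used for the kNN graph.
#' @slot ka index of the neighbor whose distance sets the per-cell kernel
#'   bandwidth.
#' @slot npcs number of principal components the graph was built in.
#'
#' @seealso [buildDiffusionOperator()], [imputeExpression()]
#' @export
setClass("DiffusionOperator", representation(
    transitions = "matrix",
    k = "integer",
    ka = "integer",
    npcs = "integer"
))

setValidity("DiffusionOperator", function(object) {
    P <- object@transitions
    if (nrow(P) != ncol(P))
        return("transition matrix must be square")
    if (nrow(P) > 0L) {
        if (any(P < 0))
            return("transition probabilities must be non-negative")
        if (max(abs(rowSums(P) - 1)) > 1e-9)
            return("rows of the transition matrix must sum to 1 (tol 1e-9)")
    }
    TRUE
})

#' Density-peak cluster model
#'
#' Per-cell local density (rho), distance to the nearest denser cell
#' (delta), the automatically chosen thresholds, the cluster centers and the
#' resulting hard assignment.
#'
#' @slot cluster integer cluster id per cell.
#' @slot rho per-cell local density (neighbor count within the kernel
#'   distance).
#' @slot delta per-cell distance to the nearest higher-density cell; the
#'   global density maximum gets the maximum pairwise distance.
#' @slot centers indices of the cells chosen as cluster centers.
#' @slot dc kernel distance used for the density estimate.
#' @slot rhoThreshold,deltaThreshold thresholds a center must exceed.
#'
#' @seealso [clusterDensityPeak()]
#' @export
setClass("ClusterModel", representation(
    cluster = "integer",
    rho = "numeric",
    delta = "numeric",
    centers = "integer",
    dc = "numeric",
    rhoThreshold = "numeric",
    deltaThreshold = "numeric"
))

setValidity("ClusterModel", function(object) {
    if (length(object@cluster) != length(object@rho) ||
        length(object@rho) != length(object@delta))
        return("cluster, rho and delta must have one entry per cell")
    if (length(object@cluster) &&
        !all(seq_len(max(object@cluster)) %in% object@cluster))
        return("every cluster id must have at least one cell")
    TRUE
})

#' Branching pseudotime trajectory
#'
#' Minimum-spanning-tree trajectory over cluster centroids in a reduced
#' space: each cell is projected onto the tree, pseudotime is the geodesic
#' distance from the root along tree edges, branch points are tree nodes of
#' degree >= 3, and branches are the maximal branch-point-free segments.
#'
#' @slot embedding cells x d reduced coordinates the tree was fitted in.
#' @slot cluster integer cluster id per cell.
#' @slot centroids cluster centroids (clusters x d).
#' @slot edges two-column integer matrix of tree edges (cluster ids).
#' @slot edgeLengths Euclidean length of each edge.
#' @slot root root cluster id.
#' @slot pseudotime per-cell geodesic distance from the root.
#' @slot cellEdge index (into rows of `edges`) of the edge each cell
#'   projects onto; NA for a single-node tree.
#' @slot cellOffset position along that edge in [0, 1], measured from the
#'   first endpoint.
#' @slot branch integer branch (segment) id per cell.
#' @slot branchPoints cluster ids of tree nodes with degree >= 3.
#'
#' @seealso [fitPrincipalTree()], [assignBranches()]
#' @export
setClass("TrajectoryModel", representation(
    embedding = "matrix",
    cluster = "integer",
    centroids = "matrix",
    edges = "matrix",
    edgeLengths = "numeric",
    root = "integer",
    pseudotime = "numeric",
    cellEdge = "integer",
    cellOffset = "numeric",
    branch = "integer",
    branchPoints = "integer"
))

setValidity("TrajectoryModel", function(object) {
    n <- nrow(object@embedding)
    if (length(object@pseudotime) != n || length(object@cluster) != n)
        return("pseudotime and cluster must have one entry per cell")
    if (length(object@pseudotime) && min(object@pseudotime) < -1e-9)
        return("pseudotime must be non-negative")
    TRUE
})

#' Preranked enrichment result
#'
#' Enrichment of one gene set in one signed ranked gene list: the weighted
#' Kolmogorov-Smirnov enrichment score, its sign-stratified normalized
#' score, a gene-label permutation p-value and the leading-edge genes.
#'
#' @slot set name of the gene set.
#' @slot es enrichment score in [-1, 1].
#' @slot nes normalized enrichment score (ES over the mean absolute
#'   same-sign null ES); NA when no same-sign null scores exist.
#' @slot pval permutation p-value with the +1 correction, so the smallest
#'   attainable value is 1/(nPerm + 1).
#' @slot leadingEdge genes driving the enrichment-score extremum.
#' @slot size number of set genes present in the ranked list.
#' @slot nPerm number of permutations used for the null.
#'
#' @seealso [gseaPreranked()], [leadingEdge()]
#' @export
setClass("EnrichmentResult", representation(
    set = "character",
    es = "numeric",
    nes = "numeric",
    pval = "numeric",
    leadingEdge = "character",
    size = "integer",
    nPerm = "integer"
))

setValidity("EnrichmentResult", function(object) {
    if (abs(object@es) > 1 + 1e-12)
        return("|ES| must not exceed 1")
    if (!is.na(object@pval) &&
        (object@pval < 1 / (object@nPerm + 1) - 1e-12 || object@pval > 1))
        return("p-value must lie in [1/(nPerm+1), 1]")
    TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nCells, "cells x", object@nGenes, "genes,",
        object@nSpikes, "spike-ins\n")
    cat("  divisions", paste(range(object@divisions), collapse = "-"),
        "| branch at division", object@branchDivision,
        "| ASC fraction", object@ascFraction, "\n")
    cat("  mRNA scale/division", object@mrnaScalePerDivision,
        "| NB dispersion", object@nbDispersion,
        "| seed", object@seed, "\n")
})

setMethod("show", "DiffusionOperator", function(object) {
    cat("DiffusionOperator over", nrow(object@transitions), "cells",
        sprintf("(k = %d, ka = %d, %d PCs)\n",
                object@k, object@ka, object@npcs))
})

setMethod("show", "ClusterModel", function(object) {
    cat("ClusterModel:", length(object@cluster), "cells in",
        length(object@centers), "clusters",
        sprintf("(dc = %.4g, rho > %.4g, delta > %.4g)\n",
                object@dc, object@rhoThreshold, object@deltaThreshold))
})

setMethod("show", "TrajectoryModel", function(object) {
    cat("TrajectoryModel:", nrow(object@embedding), "cells,",
        nrow(object@centroids), "tree nodes,",
        nrow(object@edges), "edges\n")
    cat("  root node", object@root, "|",
        length(object@branchPoints), "branch point(s) |",
        length(unique(object@branch)), "branch(es)\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult '%s': ES = %.3f, NES = %.3f, p = %.4g\n",
                object@set, object@es, object@nes, object@pval))
    cat("  set size", object@size, "| leading edge",
        length(object@leadingEdge), "genes |", object@nPerm,
        "permutations\n")
})
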