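#' Accessors for simulation and enrichment objects
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x an object.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeReference", function(x) standardGeneric("spikeReference"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("programMeans", function(x) standardGeneric("programMeans"))

#' @rdname accessors
#' @export
setGeneric("geneModules", function(x) standardGeneric("geneModules"))

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname accessors
#' @export
setGeneric("branchPoints", function(x) standardGeneric("branchPoints"))

#' @rdname accessors
#' @export
setGeneric("enrichmentScore", function(x) standardGeneric("enrichmentScore"))

#' @rdname accessors
#' @export
setGeneric("normalizedScore", function(x) standardGeneric("normalizedScore"))

#' @rdname accessors
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))

#' @rdname accessors
#' @export
setGeneric("leadingEdge", function(x) standardGeneric("leadingEdge"))

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "DiffusionOperator",
          function(x) x@transitions)

#' @rdname accessors
#' @export
setMethod("clusterIds", "ClusterModel", function(x) x@cluster)

#' @rdname accessors
#' @export
setMethod("clusterIds", "TrajectoryModel", function(x) x@cluster)

#' @rdname accessors
#' @export
setMethod("pseudotime", "TrajectoryModel", function(x) x@pseudotime)

#' @rdname accessors
#' @export
setMethod("branchPoints", "TrajectoryModel", function(x) x@branchPoints)

#' @rdname accessors
#' @export
setMethod("enrichmentScore", "EnrichmentResult", function(x) x@es)

#' @rdname accessors
#' @export
setMethod("normalizedScore", "EnrichmentResult", function(x) x@nes)

#' @rdname accessors
#' @export
setMethod("permutationP", "EnrichmentResult", function(x) x@pval)

#' @rdname accessors
#' @export
setMethod("leadingEdge", "EnrichmentResult", function(x) x@leadingEdge)
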