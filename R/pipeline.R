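#' Run the full synthetic-to-trajectory analysis pipeline
#'
#' Executes every stage on a simulated experiment: simulate single cells
#' and the bulk reference panel; QC filter and normalize; build the
#' diffusion operator and impute; annotate cells against the panel
#' (cell-type and division tracks); cluster, select ordering genes and fit
#' the branching pseudotime; run preranked enrichment of the marker-module
#' gene sets between the post-bifurcation branches; and score simulated
#' regulons with the activity/expression correlation. Per-stage tables are
#' written under `outDir` (when given) together with a JSON summary, and
#' the full set of intermediate objects is returned invisibly. All
#' randomness derives from `config@seed`, so reruns with the same
#' configuration reproduce every output.
#'
#' @param config a [SimConfig-class]; alternatively a named list or a
#'   YAML/JSON path accepted by [readPipelineConfig()], whose
#'   [simConfig()] keys build the configuration and whose remaining keys
#'   override stage parameters.
#' @param outDir output directory; `NULL` skips writing.
#' @param params named list of stage-parameter overrides (`numDim`, `k`,
#'   `ka`, `npcs`, `t`, `minCellsPerGene`, `minUmiPerCell`, `nTop`,
#'   `nPerm`, `topFraction`, `perplexity`).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the simulation, panel, filtered/imputed
#'   data, annotations, cluster and trajectory models, enrichment results,
#'   regulon output and the `summary` list written as JSON.
#' @export
runPipeline <- function(config, outDir = NULL, params = list(),
                        verbose = FALSE) {
    if (is.character(config)) config <- readPipelineConfig(config)
    if (is.list(config)) {
        simKeys <- intersect(names(config), names(formals(simConfig)))
        params <- utils::modifyList(
            params, config[setdiff(names(config),
                                   c(simKeys, "outDir", "verbose"))])
        if (!is.null(config$outDir) && is.null(outDir))
            outDir <- config$outDir
        config <- do.call(simConfig, config[simKeys])
    }
    p <- utils::modifyList(list(numDim = 10, perplexity = 30, k = 30,
                                ka = 10, npcs = 20, t = 3,
                                minCellsPerGene = 10, minUmiPerCell = 1000,
                                nTop = 1000, nPerm = 1000,
                                topFraction = 0.05), params)
    say <- function(...) if (verbose) message(...)

    say("simulating ", config@nCells, " cells x ", config@nGenes, " genes")
    sim <- simulateExperiment(config)
    panel <- simulateBulkReference(config, sim)

    say("QC filtering")
    filtered <- qcFilter(sim, p$minCellsPerGene, p$minUmiPerCell)
    filtered <- libsizeSqrtTransform(filtered)
    filtered <- logNormalize(filtered)

    say("diffusion imputation (t = ", p$t, ")")
    op <- buildDiffusionOperator(filtered, k = p$k, ka = p$ka,
                                 npcs = p$npcs, assay = "sqrtnorm")
    filtered <- imputeExpression(filtered, op, t = p$t, assay = "sqrtnorm")

    say("reference annotation")
    cellType <- annotateCells(filtered, panel, track = "cellType")
    divisionAnn <- annotateCells(filtered, panel, track = "division")
    SummarizedExperiment::colData(filtered)$cellTypeAnnotation <-
        cellType$label
    SummarizedExperiment::colData(filtered)$divisionAnnotation <-
        divisionAnn$label

    say("clustering and trajectory")
    emb <- reduceDims(filtered, numDim = p$numDim, assay = "lognorm")
    coords <- embed2d(emb, perplexity = p$perplexity)
    clusters <- clusterDensityPeak(coords)
    ordering <- selectOrderingGenes(filtered, clusters, nTop = p$nTop,
                                    assay = "lognorm")
    embOrd <- reduceDims(
        SummarizedExperiment::assay(filtered, "lognorm")[ordering, ,
                                                         drop = FALSE],
        numDim = min(p$numDim, length(ordering)))
    traj <- fitPrincipalTree(embOrd, clusters,
                             rootLabels = cellType$label, rootLabel = "nB")

    say("branch enrichment (", p$nPerm, " permutations)")
    truth <- groundTruth(filtered)
    postA <- which(truth$branch == "ASC-destined" & truth$state == "actB" &
                   truth$division > config@branchDivision)
    postN <- which(truth$branch == "non-ASC" &
                   truth$division > config@branchDivision)
    modules <- geneModules(filtered)
    moduleSets <- split(names(modules), modules)
    moduleSets <- moduleSets[setdiff(names(moduleSets), "none")]
    enrichment <- list()
    if (length(postA) >= 3 && length(postN) >= 3) {
        de <- bulkDE(
            SummarizedExperiment::assay(filtered, "lognorm")[, postA,
                                                             drop = FALSE],
            SummarizedExperiment::assay(filtered, "lognorm")[, postN,
                                                             drop = FALSE])
        ranked <- rankGenes(de$p, de$log2FC, genes = de$gene)
        enrichment <- lapply(names(moduleSets), function(s)
            gseaPreranked(ranked, moduleSets[[s]], nPerm = p$nPerm,
                          seed = config@seed, setName = s))
        names(enrichment) <- names(moduleSets)
    }

    say("regulon activity")
    regulons <- simulateRegulons(filtered, seed = config@seed)
    activity <- scoreRegulons(
        SummarizedExperiment::assay(filtered, "imputed"), regulons,
        topFraction = p$topFraction)
    regCor <- if (length(postA) && length(postN))
        activityExpressionCorrelation(
            SummarizedExperiment::assay(filtered, "imputed"),
            activity, postA, postN)
    else NULL

    branchTab <- table(truth$branch, traj@branch)
    summary <- list(
        seed = config@seed,
        nCellsSimulated = config@nCells,
        nCellsAnalyzed = ncol(filtered),
        nGenesRetained = nrow(filtered),
        nClusters = length(unique(clusters@cluster)),
        nBranchPoints = length(traj@branchPoints),
        nBranches = length(unique(traj@branch)),
        cellTypeAccuracy = mean(.truthCellType(truth) == cellType$label),
        divisionWithinOneStep = mean(.divisionStepError(
            truthDivisionLabel(filtered), divisionAnn$label) <= 1),
        branchAdjustedRandIndex = adjustedRandIndex(
            truth$branch, traj@branch),
        enrichment = lapply(enrichment, function(e)
            list(es = e@es, nes = e@nes, p = e@pval,
                 leadingEdge = length(e@leadingEdge))),
        regulonCorrelation = if (is.null(regCor)) NA else regCor$r)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeMtxTriplet(sim, file.path(outDir, "counts"))
        utils::write.table(
            data.frame(cell = colnames(filtered),
                       cluster = clusters@cluster,
                       pseudotime = traj@pseudotime,
                       branch = traj@branch,
                       cellType = cellType$label,
                       division = divisionAnn$label),
            file.path(outDir, "trajectory_cells.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(from = traj@edges[, 1], to = traj@edges[, 2],
                       length = traj@edgeLengths),
            file.path(outDir, "tree_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        writeTsvMatrix(coords, file.path(outDir, "embedding2d.tsv"),
                       idColumn = "cell")
        utils::write.table(regulons, file.path(outDir, "regulons.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(list(sim = sim, panel = panel, filtered = filtered,
                   operator = op, cellType = cellType,
                   divisionAnnotation = divisionAnn, clusters = clusters,
                   orderingGenes = ordering, trajectory = traj,
                   coords = coords, enrichment = enrichment,
                   regulons = regulons, activity = activity,
                   regulonCorrelation = regCor, summary = summary))
}

.truthCellType <- function(truth) {
    ifelse(truth$state %in% c("ASC", "ASC_ER"), "ASC",
           ifelse(truth$state == "nB", "nB", "actB"))
}

## Steps between two labels on the division reference ladder
## (div0, div1, div3, div5, div8-, div8+).
.divisionStepError <- function(truthLabel, predLabel) {
    ladder <- c("div0", "div1", "div3", "div5", "div8-", "div8+")
    abs(match(truthLabel, ladder) - match(predLabel, ladder))
}

#' Adjusted Rand index between two partitions
#'
#' Standard pair-counting agreement between two labelings, corrected for
#' chance; 1 means identical partitions, 0 the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjustedRandIndex <- function(a, b) {
    if (length(a) != length(b)) stop("partitions must have equal length")
    tab <- table(a, b)
    ch2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(ch2(tab))
    sumI <- sum(ch2(rowSums(tab)))
    sumJ <- sum(ch2(colSums(tab)))
    n <- ch2(length(a))
    expected <- sumI * sumJ / n
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(1)
    (sumIJ - expected) / (maxIdx - expected)
}
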