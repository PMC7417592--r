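#' Create a simulation configuration
#'
#' Builds a validated [SimConfig-class] describing a division-structured
#' B-cell activation experiment: cells occupy divisions 0-8 with a
#' triangular occupancy peaking at divisions 5-6, total mRNA content grows
#' multiplicatively with division, lineages bifurcate after
#' `branchDivision` into an ASC-destined branch (ASC/OXPHOS programs up,
#' Sell-analog down) and a non-ASC branch (Sell-analog retained,
#' inflammatory program up), and terminal ASC sub-split into an ER-stress
#' state. A constant spike-in pool is added to every cell.
#'
#' @param nCells,nGenes,nSpikes dimensions of the simulated experiment.
#' @param divisions division indices cells may occupy.
#' @param branchDivision division at which lineages split.
#' @param ascFraction probability a cell is a terminal ASC (division 8 on
#'   the ASC-destined branch).
#' @param erStressFraction proportion of terminal ASC in the ER-stress
#'   sub-state.
#' @param branchBias probability a non-terminal post-branch cell follows the
#'   ASC-destined branch.
#' @param mrnaScalePerDivision multiplicative total-mRNA growth per division.
#' @param moduleSizes named gene counts for the marker modules
#'   (`asc`, `bcell`, `oxphos`, `inflam`, `erstress`, `activation`); by
#'   default scaled to the gene count (60/60/80/60/40/60 at 1500 genes).
#' @param nbDispersion negative-binomial dispersion of UMI counts
#'   (0 gives Poisson counts).
#' @param libsizeCV coefficient of variation of per-cell capture efficiency.
#' @param programWalkSd per-gene log-scale sd of the division-to-division
#'   random walk superimposed on the deterministic module ramps. Successive
#'   division states inherit a common trunk and the two branches walk
#'   independently after the branch point, so division states are distinct
#'   transcriptomic islands whose distance grows with division lag —
#'   emulating the progressive genome-wide reprogramming seen across
#'   sorted divisions. 0 disables the walk.
#' @param baseLibSize expected biological UMI per cell at division 0
#'   (mid-range droplet yield at this gene-panel size).
#' @param spikePoolSize expected spike-in UMI per cell.
#' @param bulkReplicates replicates per bulk reference label.
#' @param bulkNoiseSd lognormal sd of bulk replicate noise (0 = noise free).
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nCells = 100, nGenes = 400, seed = 7)
#' cfg
#' @export
simConfig <- function(nCells = 2000, nGenes = 1500, nSpikes = 50,
                      divisions = 0:8, branchDivision = 3,
                      ascFraction = 0.1, erStressFraction = 0.3,
                      branchBias = 0.5, mrnaScalePerDivision = 1.3,
                      moduleSizes = NULL,
                      nbDispersion = 0.2, libsizeCV = 0.3,
                      programWalkSd = 0.25,
                      baseLibSize = 3000, spikePoolSize = 300,
                      bulkReplicates = 3, bulkNoiseSd = 0.15, seed = 1) {
    if (length(nCells) != 1L || is.na(nCells) || nCells < 0)
        stop("nCells must be a single non-negative number")
    if (length(nGenes) != 1L || is.na(nGenes) || nGenes <= 0)
        stop("nGenes must be a single positive number")
    wanted <- c("asc", "bcell", "oxphos", "inflam", "erstress", "activation")
    if (is.null(moduleSizes))
        moduleSizes <- round(nGenes * c(asc = 0.04, bcell = 0.04,
                                        oxphos = 8 / 150, inflam = 0.04,
                                        erstress = 4 / 150,
                                        activation = 0.04))
    if (!all(wanted %in% names(moduleSizes)))
        stop("moduleSizes must name the modules: ",
             paste(wanted, collapse = ", "))
    new("SimConfig",
        nCells = as.integer(nCells), nGenes = as.integer(nGenes),
        nSpikes = as.integer(nSpikes),
        divisions = sort(unique(as.integer(divisions))),
        branchDivision = as.integer(branchDivision),
        ascFraction = as.numeric(ascFraction),
        erStressFraction = as.numeric(erStressFraction),
        branchBias = as.numeric(branchBias),
        mrnaScalePerDivision = as.numeric(mrnaScalePerDivision),
        moduleSizes = vapply(moduleSizes[wanted], as.integer, integer(1)),
        nbDispersion = as.numeric(nbDispersion),
        libsizeCV = as.numeric(libsizeCV),
        programWalkSd = as.numeric(programWalkSd),
        baseLibSize = as.numeric(baseLibSize),
        spikePoolSize = as.numeric(spikePoolSize),
        bulkReplicates = as.integer(bulkReplicates),
        bulkNoiseSd = as.numeric(bulkNoiseSd),
        seed = as.integer(seed))
}

## Recognizable marker aliases heading each module; the rest of a module is
## anonymous. Aliases claim the qualitative behavior only, not real genes.
.moduleAliases <- list(
    asc = c("Prdm1_like", "Xbp1_like", "Irf4_like", "Sdc1_like",
            "Jchain_like", "Ell2_like"),
    bcell = c("Sell_like", "Pax5_like", "Ciita_like", "Spib_like"),
    naive = c("Fcer2a_like", "Cr2_like"),
    oxphos = c("Myc_like", "Ldha_like", "Idh3a_like", "Srm_like",
               "Dut_like"),
    inflam = c("Klf6_like", "Ifngr1_like", "Nfkbia_like"),
    erstress = c("Atf6_like", "Hspa5_like", "Calr_like", "Dnajb9_like"),
    activation = c("Zbtb32_like", "Aicda_like", "Ezh2_like", "Batf_like"))

.moduleGeneNames <- function(module, n) {
    alias <- .moduleAliases[[module]]
    if (n <= length(alias)) return(alias[seq_len(n)])
    c(alias, sprintf("%s%03d", toupper(substr(module, 1, 3)),
                     seq_len(n - length(alias))))
}

## Gene module layout: the bcell entry of moduleSizes is split into a
## Sell-like half (lost only on the ASC-destined branch) and a naive half
## (declining with division in every cell).
.geneLayout <- function(config) {
    ms <- config@moduleSizes
    nSell <- ceiling(ms[["bcell"]] / 2)
    nNaive <- ms[["bcell"]] - nSell
    sizes <- c(asc = ms[["asc"]], bcell = nSell, naive = nNaive,
               oxphos = ms[["oxphos"]], inflam = ms[["inflam"]],
               erstress = ms[["erstress"]], activation = ms[["activation"]])
    module <- rep(names(sizes), sizes)
    nFree <- config@nGenes - length(module)
    module <- c(module, rep("none", nFree))
    names <- character(config@nGenes)
    idx <- 1L
    for (m in names(sizes)) {
        if (sizes[[m]] == 0L) next
        names[idx:(idx + sizes[[m]] - 1L)] <- .moduleGeneNames(m, sizes[[m]])
        idx <- idx + sizes[[m]]
    }
    if (nFree > 0L)
        names[idx:config@nGenes] <- sprintf("G%04d", seq_len(nFree))
    list(module = module, names = names)
}

## Module multiplier for one program context.
## u = division/8 overall progress, v = post-branch progress in [0,1],
## ctx one of "pre", "non", "ascb" (ASC-destined actB), "ASC", "ASC_ER".
## The activation response is immediate-early and saturating (sqrt ramp in
## division), as in LPS blasts; branch programs ramp with post-branch
## progress; terminal ASC carry the full secretory phenotype.
.moduleMultiplier <- function(module, u, v, ctx) {
    terminal <- ctx %in% c("ASC", "ASC_ER")
    su <- sqrt(u)
    switch(module,
        activation = if (terminal) 1.5 else 0.2 + 4.8 * su,
        naive = if (terminal) 0.05 else 1 - 0.9 * su,
        bcell = if (terminal) 0.08
                else if (ctx == "ascb") 1 - 0.85 * v else 1,
        asc = if (terminal) 6
              else if (ctx == "ascb") 0.05 + 1.95 * v else 0.05,
        oxphos = if (terminal) 4
                 else (1 + 0.6 * u) * (if (ctx == "ascb") 1 + 2 * v else 1),
        inflam = if (terminal) 0.6
                 else if (ctx == "non") 1 + 2.5 * v else 1,
        erstress = if (ctx == "ASC_ER") 7
                   else if (ctx == "ASC") 2.5
                   else if (ctx == "ascb") 1 + v else 1,
        none = 1)
}

## Table of expression programs implied by a config: one per pre-branch
## division, two per post-branch division, plus the two terminal ASC states.
.programTable <- function(config) {
    bp <- config@branchDivision
    dMax <- max(config@divisions)
    rows <- list()
    for (d in config@divisions) {
        if (d < bp) {
            rows[[length(rows) + 1L]] <-
                data.frame(program = paste0("pre_", d), division = d,
                           ctx = "pre", stringsAsFactors = FALSE)
        } else {
            rows[[length(rows) + 1L]] <-
                data.frame(program = paste0("asc_", d), division = d,
                           ctx = "ascb", stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <-
                data.frame(program = paste0("non_", d), division = d,
                           ctx = "non", stringsAsFactors = FALSE)
        }
    }
    rows[[length(rows) + 1L]] <- data.frame(program = "ASC",
                                            division = dMax, ctx = "ASC",
                                            stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(program = "ASC_ER",
                                            division = dMax, ctx = "ASC_ER",
                                            stringsAsFactors = FALSE)
    do.call(rbind, rows)
}

## Per-gene log-scale random walk along the division ladder: one shared
## trunk before the branch point; after it, each division step splits into
## a division-shared component (cell-cycle/metabolic reprogramming common
## to both dividing lineages) and a branch-specific component of equal
## variance, so branch profiles diverge while division identity remains
## shared. One further step leads into the terminal ASC state (shared by
## the ER-stress sub-state, which differs from plain ASC only in the
## ER-chaperone module). Step size scales with sqrt(division gap).
.programWalk <- function(config, progTab) {
    sigma <- config@programWalkSd
    walk <- matrix(0, nrow = config@nGenes, ncol = nrow(progTab),
                   dimnames = list(NULL, progTab$program))
    if (sigma == 0) return(walk)
    bp <- config@branchDivision
    step <- function(gap, frac = 1)
        stats::rnorm(config@nGenes) * sigma * sqrt(gap * frac)
    statePre <- numeric(config@nGenes)
    stateAsc <- stateNon <- NULL
    prevD <- min(config@divisions)
    for (d in config@divisions) {
        gap <- max(d - prevD, ifelse(d == min(config@divisions), 0, 1))
        if (d < bp) {
            statePre <- statePre + step(gap)
            walk[, paste0("pre_", d)] <- statePre
        } else {
            if (is.null(stateAsc)) stateAsc <- stateNon <- statePre
            shared <- step(gap, 0.6)
            stateAsc <- stateAsc + shared + step(gap, 0.4)
            stateNon <- stateNon + shared + step(gap, 0.4)
            walk[, paste0("asc_", d)] <- stateAsc
            walk[, paste0("non_", d)] <- stateNon
        }
        prevD <- d
    }
    terminal <- (if (is.null(stateAsc)) statePre else stateAsc) + step(1)
    walk[, "ASC"] <- terminal
    walk[, "ASC_ER"] <- terminal
    walk
}

## Gene x program matrix of expected per-cell UMI. Each program column sums
## to baseLibSize * mrnaScalePerDivision^division, so total mRNA content
## grows deterministically with division.
.buildProgramMeans <- function(config, baseWeight, layout) {
    progTab <- .programTable(config)
    bp <- config@branchDivision
    dMax <- max(config@divisions)
    span <- max(1L, dMax - bp)
    walk <- .programWalk(config, progTab)
    pm <- matrix(0, nrow = config@nGenes, ncol = nrow(progTab),
                 dimnames = list(layout$names, progTab$program))
    for (j in seq_len(nrow(progTab))) {
        d <- progTab$division[j]
        ctx <- progTab$ctx[j]
        u <- min(1, d / max(1L, dMax))
        v <- if (ctx %in% c("ASC", "ASC_ER")) 1
             else max(0, min(1, (d - bp) / span))
        mult <- vapply(layout$module, .moduleMultiplier, numeric(1),
                       u = u, v = v, ctx = ctx)
        prof <- baseWeight * mult * exp(walk[, j])
        prof <- prof / sum(prof) *
            config@baseLibSize * config@mrnaScalePerDivision^d
        pm[, j] <- prof
    }
    attr(pm, "programInfo") <- progTab
    pm
}

## Division occupancy resembling a 72 h CTV profile: a triangular
## responder distribution peaking between divisions 5 and 6, plus a
## non-responder mass of undivided cells at division 0.
.divisionOccupancy <- function(divisions, nonResponder = 0.10) {
    w <- 1 - abs(divisions - 5.5) / 8
    w <- pmax(w, 0.02)
    w <- w / sum(w)
    if (0 %in% divisions) {
        w <- w * (1 - nonResponder)
        w[divisions == 0] <- w[divisions == 0] + nonResponder
    }
    w
}

#' Simulate a division-structured single-cell experiment
#'
#' Draws UMI counts for activated B cells spanning the configured divisions:
#' per-cell expected expression is a program mean (set by division, branch
#' and state) scaled by the division-dependent total-mRNA factor and a
#' lognormal per-cell capture efficiency applied equally to genes and
#' spike-ins; counts are negative binomial. Spike-in counts are drawn from a
#' division-independent constant pool scaled only by capture efficiency, so
#' the spike-in share of a cell's library shrinks as total mRNA grows.
#'
#' The result carries the full ground truth: per-cell division, branch
#' (`pre-branch`, `ASC-destined`, `non-ASC`), state (`nB`, `actB`, `ASC`,
#' `ASC_ER`) and generating program in `colData`; per-gene module membership
#' in `rowData`; the gene-by-program mean matrix, the configuration and the
#' spike-in reference in `metadata`. Spike-in counts live in
#' `altExp(x, "ERCC")`.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay of raw UMI (genes x cells).
#' @examples
#' sim <- simulateExperiment(simConfig(nCells = 50, nGenes = 400, seed = 1))
#' table(groundTruth(sim)$branch)
#' @export
simulateExperiment <- function(config) {
    if (!is(config, "SimConfig")) stop("config must be a SimConfig")
    validObject(config)
    set.seed(config@seed)
    layout <- .geneLayout(config)
    baseWeight <- stats::rlnorm(config@nGenes, meanlog = 0, sdlog = 1)
    spikeWeight <- stats::rlnorm(config@nSpikes, meanlog = 0, sdlog = 0.8)
    spikeIds <- sprintf("ERCC-%04d", seq_len(config@nSpikes))
    spikeMolecules <- spikeWeight
    spikeCountMean <- if (config@nSpikes > 0L)
        spikeWeight / sum(spikeWeight) * config@spikePoolSize
    else numeric(0)

    pm <- .buildProgramMeans(config, baseWeight, layout)
    progTab <- attr(pm, "programInfo")
    n <- config@nCells
    bp <- config@branchDivision
    dMax <- max(config@divisions)

    if (n > 0L) {
        isASC <- stats::runif(n) < config@ascFraction
        division <- integer(n)
        division[isASC] <- dMax
        nOther <- sum(!isASC)
        occ <- .divisionOccupancy(config@divisions)
        division[!isASC] <- sample(config@divisions, nOther, replace = TRUE,
                                   prob = occ)
        onAscBranch <- stats::runif(n) < config@branchBias
        isER <- stats::runif(n) < config@erStressFraction

        state <- ifelse(isASC, ifelse(isER, "ASC_ER", "ASC"),
                        ifelse(division == 0L, "nB", "actB"))
        branch <- ifelse(division < bp, "pre-branch",
                         ifelse(isASC | onAscBranch,
                                "ASC-destined", "non-ASC"))
        program <- ifelse(isASC, ifelse(isER, "ASC_ER", "ASC"),
                   ifelse(division < bp, paste0("pre_", division),
                   ifelse(onAscBranch, paste0("asc_", division),
                          paste0("non_", division))))

        s2 <- log(1 + config@libsizeCV^2)
        capture <- stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))

        mu <- pm[, program, drop = FALSE] *
            rep(capture, each = config@nGenes)
        counts <- if (config@nbDispersion > 0)
            matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config@nbDispersion),
                   nrow = config@nGenes)
        else matrix(stats::rpois(length(mu), lambda = mu),
                    nrow = config@nGenes)
        spikeMu <- outer(spikeCountMean, capture)
        spikeCounts <- matrix(stats::rpois(length(spikeMu),
                                           lambda = spikeMu),
                              nrow = config@nSpikes)
    } else {
        division <- integer(0); state <- character(0)
        branch <- character(0); program <- character(0)
        capture <- numeric(0)
        counts <- matrix(0L, nrow = config@nGenes, ncol = 0L)
        spikeCounts <- matrix(0L, nrow = config@nSpikes, ncol = 0L)
    }
    cellIds <- sprintf("cell%05d", seq_len(n))
    dimnames(counts) <- list(layout$names, cellIds)
    dimnames(spikeCounts) <- list(spikeIds, cellIds)

    spikes <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = spikeCounts),
        rowData = S4Vectors::DataFrame(molecules = spikeMolecules,
                                       row.names = spikeIds))
    colnames(spikes) <- cellIds
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(module = layout$module,
                                       row.names = layout$names),
        colData = S4Vectors::DataFrame(division = division, branch = branch,
                                       state = state, program = program,
                                       capture = capture,
                                       row.names = cellIds))
    SingleCellExperiment::altExp(sce, "ERCC") <- spikes
    S4Vectors::metadata(sce) <- list(
        config = config,
        programMeans = pm,
        programInfo = progTab,
        spikeReference = data.frame(spike_id = spikeIds,
                                    molecules = spikeMolecules,
                                    stringsAsFactors = FALSE))
    sce
}

#' @describeIn simulateExperiment Spike-in reference table
#'   (`spike_id`, `molecules`) stored with a simulation.
#' @param x a simulated `SingleCellExperiment`.
#' @export
setMethod("spikeReference", "SingleCellExperiment", function(x) {
    S4Vectors::metadata(x)$spikeReference
})

#' @describeIn simulateExperiment Per-cell ground truth (division, branch,
#'   state, generating program).
#' @export
setMethod("groundTruth", "SingleCellExperiment", function(x) {
    SummarizedExperiment::colData(x)[,
        intersect(c("division", "branch", "state", "program"),
                  colnames(SummarizedExperiment::colData(x))), drop = FALSE]
})

#' @describeIn simulateExperiment Gene-by-program matrix of expected
#'   per-cell UMI.
#' @export
setMethod("programMeans", "SingleCellExperiment", function(x) {
    S4Vectors::metadata(x)$programMeans
})

#' @describeIn simulateExperiment Per-gene module membership.
#' @export
setMethod("geneModules", "SingleCellExperiment", function(x) {
    stats::setNames(SummarizedExperiment::rowData(x)$module, rownames(x))
})

#' Expected (noise-free) expression profile of each simulated cell
#'
#' Returns the generating program mean for every cell, i.e. the expected UMI
#' counts before capture-efficiency and counting noise. Useful as a
#' noise-free stand-in for the cells in recovery tests.
#'
#' @param sim a simulation from [simulateExperiment()].
#' @return genes x cells numeric matrix.
#' @export
cellProgramMeans <- function(sim) {
    pm <- programMeans(sim)
    out <- pm[, SummarizedExperiment::colData(sim)$program, drop = FALSE]
    colnames(out) <- colnames(sim)
    out
}

#' Ground-truth division label on the bulk reference ladder
#'
#' Maps each simulated cell's true division and state onto the label
#' vocabulary of the division-sorted bulk reference panel
#' (`div0`, `div1`, `div3`, `div5`, `div8-`, `div8+`): terminal ASC map to
#' `div8+`, division-8 undifferentiated cells to `div8-`, and every other
#' division to the nearest sorted division.
#'
#' @param sim a simulation from [simulateExperiment()].
#' @param ladder sorted divisions of the reference panel.
#' @return character vector of expected labels, one per cell.
#' @export
truthDivisionLabel <- function(sim, ladder = c(0, 1, 3, 5, 8)) {
    truth <- groundTruth(sim)
    vapply(seq_len(nrow(truth)), function(i) {
        d <- truth$division[i]
        if (d == max(ladder)) {
            if (truth$state[i] %in% c("ASC", "ASC_ER")) "div8+" else "div8-"
        } else {
            near <- ladder[which.min(abs(ladder - d))]
            if (near == max(ladder)) "div8-" else paste0("div", near)
        }
    }, character(1))
}

#' Simulate a labeled bulk reference panel
#'
#' Emits `bulkReplicates` replicate expression profiles for each reference
#' label: the division ladder (`div0`, `div1`, `div3`, `div5`, `div8-`,
#' `div8+`; restricted to simulated divisions) and the cell types (`nB`,
#' `actB`, `ASC`). Each profile is the population-expected per-cell
#' expression at that label (post-branch divisions are branch mixtures, as
#' in a division sort), with spike-in rows appended and multiplicative
#' lognormal replicate noise of sd `bulkNoiseSd` (0 gives identical
#' replicates).
#'
#' @param config a [SimConfig-class].
#' @param sim optional simulation from [simulateExperiment()] whose program
#'   means should be reused; when missing, programs are rebuilt from
#'   `config` (identical by construction, since gene weights depend only on
#'   the seed).
#' @return A [SummarizedExperiment::SummarizedExperiment] with an `fpkm`
#'   assay ((genes + spikes) x replicates), `label`, `track` and `replicate`
#'   columns, a per-row `isSpike` flag, and the noise-free profiles plus the
#'   spike-in reference in `metadata`.
#' @examples
#' cfg <- simConfig(nCells = 10, nGenes = 300, bulkReplicates = 2, seed = 1)
#' panel <- simulateBulkReference(cfg)
#' table(SummarizedExperiment::colData(panel)$label)
#' @export
simulateBulkReference <- function(config, sim = NULL) {
    if (!is(config, "SimConfig")) stop("config must be a SimConfig")
    validObject(config)
    if (is.null(sim)) {
        set.seed(config@seed)
        layout <- .geneLayout(config)
        baseWeight <- stats::rlnorm(config@nGenes, 0, 1)
        spikeWeight <- stats::rlnorm(config@nSpikes, 0, 0.8)
        pm <- .buildProgramMeans(config, baseWeight, layout)
        spikeMolecules <- spikeWeight
    } else {
        pm <- programMeans(sim)
        spikeMolecules <- spikeReference(sim)$molecules
    }
    spikeIds <- sprintf("ERCC-%04d", seq_len(config@nSpikes))
    spikeCountMean <- if (config@nSpikes > 0L)
        spikeMolecules / sum(spikeMolecules) * config@spikePoolSize
    else numeric(0)

    bp <- config@branchDivision
    dMax <- max(config@divisions)
    mixAt <- function(d) {
        if (d < bp) return(pm[, paste0("pre_", d)])
        config@branchBias * pm[, paste0("asc_", d)] +
            (1 - config@branchBias) * pm[, paste0("non_", d)]
    }
    ascProfile <- (1 - config@erStressFraction) * pm[, "ASC"] +
        config@erStressFraction * pm[, "ASC_ER"]

    profiles <- list()
    meta <- list()
    for (d in intersect(c(0L, 1L, 3L, 5L), config@divisions)) {
        profiles[[paste0("div", d)]] <- mixAt(d)
        meta[[paste0("div", d)]] <- c(track = "division", division = as.character(d))
    }
    if (dMax >= bp) {
        profiles[["div8-"]] <- mixAt(dMax)
        meta[["div8-"]] <- c(track = "division", division = "8-")
        profiles[["div8+"]] <- ascProfile
        meta[["div8+"]] <- c(track = "division", division = "8+")
    }
    ## ex vivo activated blasts span the division range; weight divisions
    ## uniformly so the reference is not dominated by the occupancy peak
    actDivs <- config@divisions[config@divisions >= 1L]
    actW <- rep(1, length(actDivs))
    actProfile <- Reduce(`+`, Map(function(d, w) w * mixAt(d),
                                  actDivs, actW / sum(actW)))
    profiles[["nB"]] <- pm[, if (0L %in% config@divisions) "pre_0" else
                                 colnames(pm)[1]]
    meta[["nB"]] <- c(track = "cellType", division = NA)
    profiles[["actB"]] <- actProfile
    meta[["actB"]] <- c(track = "cellType", division = NA)
    profiles[["ASC"]] <- ascProfile
    meta[["ASC"]] <- c(track = "cellType", division = NA)

    labels <- names(profiles)
    nrep <- config@bulkReplicates
    full <- vapply(labels, function(l) c(profiles[[l]], spikeCountMean),
                   numeric(config@nGenes + config@nSpikes))
    rownames(full) <- c(rownames(pm), spikeIds)

    set.seed(config@seed + 1L)
    s <- config@bulkNoiseSd
    cols <- list(); cn <- character(0)
    label <- character(0); track <- character(0); repl <- integer(0)
    divLab <- character(0)
    for (l in labels) {
        for (r in seq_len(nrep)) {
            noise <- if (s > 0)
                stats::rlnorm(nrow(full), meanlog = -s^2 / 2, sdlog = s)
            else rep(1, nrow(full))
            cols[[length(cols) + 1L]] <- full[, l] * noise
            cn <- c(cn, paste0(l, "_rep", r))
            label <- c(label, l)
            track <- c(track, meta[[l]][["track"]])
            divLab <- c(divLab, meta[[l]][["division"]])
            repl <- c(repl, r)
        }
    }
    mat <- do.call(cbind, cols)
    dimnames(mat) <- list(rownames(full), cn)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = mat),
        rowData = S4Vectors::DataFrame(
            isSpike = c(rep(FALSE, config@nGenes),
                        rep(TRUE, config@nSpikes)),
            row.names = rownames(full)),
        colData = S4Vectors::DataFrame(label = label, track = track,
                                       division = divLab,
                                       replicate = repl, row.names = cn),
        metadata = list(trueProfiles = full,
                        spikeReference = data.frame(
                            spike_id = spikeIds,
                            molecules = spikeMolecules,
                            stringsAsFactors = FALSE),
                        config = config))
}
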