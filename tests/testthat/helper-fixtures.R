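suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(SingleCellExperiment)
})

## Shared fixtures, memoized so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

## The full default analysis: 2000 cells x 1500 genes, seed 1.
defaultPipeline <- function() {
    if (is.null(.fixtures$pipeline))
        .fixtures$pipeline <- runPipeline(simConfig(seed = 1))
    .fixtures$pipeline
}

## A small simulation for unit tests.
smallSim <- function() {
    if (is.null(.fixtures$smallSim))
        .fixtures$smallSim <- simulateExperiment(
            simConfig(nCells = 300, nGenes = 400, seed = 11))
    .fixtures$smallSim
}

## Strip the CD138 sub-label from a division annotation: div8- and div8+
## are both division 8.
divisionNumber <- function(label) {
    as.integer(sub("[+-]$", "", sub("^div", "", label)))
}

## Independent Benjamini-Hochberg step-up oracle (cumulative minimum from
## the largest p).
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(p[o] * m / (m:1)))
    out <- numeric(m)
    out[o] <- adj
    out
}

## Brute-force weighted Kolmogorov-Smirnov enrichment score: full running
## sum over all list positions, extremum by largest absolute deviation
## (ties resolved toward the positive extremum).
gseaOracle <- function(scores, isHit, weight = 1) {
    N <- length(scores)
    m <- sum(isHit)
    w <- abs(scores)^weight
    sumW <- sum(w[isHit])
    inc <- if (sumW == 0) ifelse(isHit, 1 / m, 0) else
        ifelse(isHit, w / sumW, 0)
    dec <- ifelse(isHit, 0, 1 / (N - m))
    run <- cumsum(inc - dec)
    mx <- max(run); mn <- min(c(run, 0))
    if (mx >= -mn) mx else mn
}

## Rank-AUC recovery oracle: explicit step sum of the recovery curve over
## the top window.
rankAucOracle <- function(values, targetIdx, topFraction = 0.05) {
    n <- length(values)
    nTop <- max(1L, round(topFraction * n))
    pos <- integer(n)
    pos[order(-values, seq_len(n))] <- seq_len(n)
    hits <- cumsum(seq_len(nTop) %in% pos[targetIdx])
    sum(hits) / sum(pmin(seq_len(nTop), length(targetIdx)))
}

## Cell-type implied by the generator's ground truth.
truthCellType <- function(truth) {
    ifelse(truth$state %in% c("ASC", "ASC_ER"), "ASC",
           ifelse(truth$state == "nB", "nB", "actB"))
}
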