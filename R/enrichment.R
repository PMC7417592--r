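#' Build a signed ranked gene list
#'
#' Combines per-gene p-values with the sign of the fold change into a
#' single ranking score and returns the genes in descending score order
#' (strongly up-regulated genes first, strongly down-regulated last).
#'
#' Two scoring modes are available. The default, `"complement"`, scores
#' `sign(FC) * (1 - p)` so significant genes sit at the list extremes and
#' non-significant genes in the middle — the ordering the enrichment
#' figures imply. The `"literal"` mode scores `sign(FC) * p`, the verbatim
#' reading of "p-value multiplied by the sign of the fold change"; note it
#' pushes non-significant genes to the extremes.
#'
#' @param p per-gene p-values in [0, 1].
#' @param fc per-gene fold changes (only the sign and, for tie-breaking,
#'   the magnitude are used). Genes with a missing sign are dropped with a
#'   warning.
#' @param genes gene ids; defaults to `names(p)`.
#' @param mode `"complement"` (default) or `"literal"`.
#' @return Named numeric vector of scores sorted in descending order; ties
#'   are broken by |FC| (descending) and then gene id, so the order is
#'   deterministic.
#' @examples
#' rankGenes(p = c(a = 0.01, b = 0.5, c = 0.02), fc = c(2, 1, -3))
#' @export
rankGenes <- function(p, fc, genes = names(p),
                      mode = c("complement", "literal")) {
    mode <- match.arg(mode)
    if (is.null(genes)) genes <- as.character(seq_along(p))
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    drop <- is.na(fc) | is.na(p)
    if (any(drop)) {
        warning(sum(drop), " gene(s) dropped for missing p or fold-change sign")
        p <- p[!drop]; fc <- fc[!drop]; genes <- genes[!drop]
    }
    score <- if (mode == "complement") sign(fc) * (1 - p) else sign(fc) * p
    ord <- order(-score, -abs(fc), genes)
    stats::setNames(score[ord], genes[ord])
}

## Enrichment score of a hit-position set in a ranked list of length N.
## wAbs: |score|^weight at the hit positions (in hit order).
## Returns the ES, the extremum type and the hit index attaining it.
.gseaES <- function(hitPos, wAbs, N) {
    m <- length(hitPos)
    sumW <- sum(wAbs)
    inc <- if (sumW == 0) rep(1 / m, m) else wAbs / sumW
    d <- if (N == m) 0 else 1 / (N - m)
    cw <- cumsum(inc)
    after <- cw - (hitPos - seq_len(m)) * d       # running sum just after hit j
    before <- after - inc                          # just before hit j
    maxPos <- max(after)
    minNeg <- min(c(before, 0))
    if (maxPos >= -minNeg) {
        list(es = maxPos, atHit = which.max(after), positive = TRUE)
    } else {
        list(es = minNeg, atHit = which.min(before), positive = FALSE)
    }
}

#' Preranked gene-set enrichment with a permutation null
#'
#' Computes the weighted Kolmogorov-Smirnov enrichment score of a gene set
#' in a signed ranked list: walking down the list, set members increment
#' the running sum by `|score|^weight` (normalized over the set) and
#' non-members decrement it by `1/(N - Nhits)`; the enrichment score (ES)
#' is the extremum of the running sum. The null distribution is obtained
#' by permuting set membership over list positions (gene-label
#' permutation), giving `p = (1 + #{|ES_perm| >= |ES|}) / (nPerm + 1)` —
#' so with 1000 permutations the smallest attainable p is 1/1001 — and a
#' sign-stratified normalized score `NES = ES / mean(|same-sign ES_perm|)`.
#' The leading edge contains the set members at or before the running-sum
#' maximum (ES > 0) or at or after its minimum (ES < 0).
#'
#' @param ranked named numeric vector of ranking scores sorted in
#'   descending order (from [rankGenes()]).
#' @param geneset character vector of gene ids; at least one must be
#'   present in `ranked`.
#' @param weight exponent on |score| for hit increments (1 = standard
#'   weighted statistic; 0 = classic Kolmogorov-Smirnov).
#' @param nPerm number of membership permutations.
#' @param seed seed for the permutation draw.
#' @param setName label stored in the result.
#' @return An [EnrichmentResult-class].
#' @examples
#' ranked <- rankGenes(p = seq(0.01, 0.5, length.out = 20),
#'                     fc = rep(c(1, -1), 10),
#'                     genes = paste0("g", 1:20))
#' gseaPreranked(ranked, c("g1", "g3", "g5"), nPerm = 100)
#' @export
gseaPreranked <- function(ranked, geneset, weight = 1, nPerm = 1000,
                          seed = 1, setName = "geneset") {
    genes <- names(ranked)
    hitPos <- which(genes %in% geneset)
    if (length(hitPos) == 0L)
        stop("no gene of the set is present in the ranked list")
    N <- length(ranked)
    m <- length(hitPos)
    wAll <- abs(ranked)^weight
    obs <- .gseaES(hitPos, wAll[hitPos], N)

    set.seed(seed)
    esPerm <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        pos <- sort.int(sample.int(N, m))
        esPerm[b] <- .gseaES(pos, wAll[pos], N)$es
    }
    pval <- (1 + sum(abs(esPerm) >= abs(obs$es))) / (nPerm + 1)
    sameSign <- esPerm[sign(esPerm) == sign(obs$es)]
    nes <- if (length(sameSign)) obs$es / mean(abs(sameSign)) else NA_real_

    le <- if (obs$es > 0) genes[hitPos[seq_len(obs$atHit)]]
          else if (obs$es < 0) genes[hitPos[obs$atHit:m]]
          else character(0)
    new("EnrichmentResult", set = setName, es = obs$es, nes = nes,
        pval = pval, leadingEdge = le, size = as.integer(m),
        nPerm = as.integer(nPerm))
}

#' Gene-set activity score per cell
#'
#' Summarizes a gene set (typically GSEA leading-edge genes or regulon
#' targets) on imputed expression: per cell, the mean expression of the
#' listed genes, cubed (`"cube-of-mean"`, the display score). Cubing is
#' monotone on the non-negative imputed values, so cell rankings equal
#' those of the plain mean; it only sharpens contrast. A `"mean-of-cubes"`
#' alternative (`mean(x^3)`) is provided for the other reading of the
#' score.
#'
#' @param expr imputed genes x cells matrix, or a `SingleCellExperiment`
#'   with an `imputed` assay.
#' @param genes gene ids to score; must intersect the matrix rows.
#' @param mode `"cube-of-mean"` (default) or `"mean-of-cubes"`.
#' @return Named numeric vector, one score per cell.
#' @export
activityScore <- function(expr, genes,
                          mode = c("cube-of-mean", "mean-of-cubes")) {
    mode <- match.arg(mode)
    m <- .assayOrMatrix(expr, "imputed")
    hit <- intersect(genes, rownames(m))
    if (length(hit) == 0L)
        stop("none of the genes are present in the expression matrix")
    sub <- m[hit, , drop = FALSE]
    if (mode == "cube-of-mean") colMeans(sub)^3 else colMeans(sub^3)
}

#' Gene expression profiles along pseudotime
#'
#' Bins cells into `nBins` equal-count pseudotime bins, averages each
#' gene's expression per bin, and scales every gene to its maximal bin
#' mean, so each nonzero row peaks at exactly 1 (all-zero genes stay 0) —
#' the normalization used for pseudotime heatmaps.
#'
#' @param expr genes x cells expression matrix (typically imputed).
#' @param pseudotime per-cell pseudotime.
#' @param genes genes to profile; default all rows.
#' @param nBins number of pseudotime bins (must not exceed the cell count).
#' @return genes x bins matrix with row maxima 1 (or 0).
#' @export
pseudotimeProfile <- function(expr, pseudotime, genes = NULL, nBins = 50) {
    m <- .assayOrMatrix(expr, "imputed")
    if (length(pseudotime) != ncol(m))
        stop("pseudotime must have one entry per cell")
    if (nBins > ncol(m))
        stop("nBins (", nBins, ") exceeds the number of cells (", ncol(m), ")")
    if (!is.null(genes)) {
        hit <- intersect(genes, rownames(m))
        if (length(hit) == 0L) stop("no requested gene found")
        m <- m[hit, , drop = FALSE]
    }
    r <- rank(pseudotime, ties.method = "first")
    bin <- ceiling(r * nBins / length(pseudotime))
    prof <- vapply(seq_len(nBins), function(b)
        rowMeans(m[, bin == b, drop = FALSE]), numeric(nrow(m)))
    prof <- matrix(prof, nrow = nrow(m),
                   dimnames = list(rownames(m), paste0("bin", seq_len(nBins))))
    mx <- apply(prof, 1, max)
    mx[mx == 0] <- 1
    prof / mx
}
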