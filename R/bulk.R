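.assayOrMatrix <- function(x, assay) {
    if (is(x, "SummarizedExperiment"))
        as.matrix(SummarizedExperiment::assay(x, assay))
    else as.matrix(x)
}

.spikeFlag <- function(x, spikePrefix = "ERCC-") {
    if (is(x, "SummarizedExperiment") &&
        "isSpike" %in% colnames(SummarizedExperiment::rowData(x)))
        return(SummarizedExperiment::rowData(x)$isSpike)
    startsWith(rownames(x), spikePrefix)
}

#' Reads-per-million normalization
#'
#' Scales every sample so its biological genes sum to one million. Spike-in
#' rows (identified by the `isSpike` row flag of a `SummarizedExperiment`
#' or by an id prefix) are excluded from the per-million denominator by
#' default but are rescaled with the same per-sample factor, so the
#' spike-to-gene ratio within a sample is preserved.
#'
#' @param x genes x samples count matrix, or a `SummarizedExperiment` with
#'   the assay named by `assay`.
#' @param assay assay holding counts when `x` is a `SummarizedExperiment`.
#' @param includeSpikes count spike-in rows inside the per-million
#'   denominator.
#' @param spikePrefix row-name prefix marking spike-ins when no `isSpike`
#'   flag is available.
#' @return For a matrix, the RPM matrix; for a `SummarizedExperiment`, the
#'   object with an `rpm` assay added.
#' @examples
#' m <- matrix(c(5, 0, 5, 15), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' rpmNormalize(m)
#' @export
rpmNormalize <- function(x, assay = "counts", includeSpikes = FALSE,
                         spikePrefix = "ERCC-") {
    m <- .assayOrMatrix(x, assay)
    spike <- .spikeFlag(x, spikePrefix)
    denom <- if (includeSpikes) colSums(m) else colSums(m[!spike, , drop = FALSE])
    bad <- which(denom <= 0)
    if (length(bad))
        stop("zero-sum column(s): ",
             paste(colnames(m)[bad] %||% bad, collapse = ", "))
    rpm <- sweep(m, 2, denom / 1e6, "/")
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "rpm") <- rpm
        x
    } else rpm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection filter across sample groups
#'
#' A gene is "detected" when at least one experimental group has every one
#' of its samples at or above `minRpm` reads per million. Raising `minRpm`
#' can only shrink the detected set.
#'
#' @param rpm genes x samples RPM matrix (or `SummarizedExperiment` with an
#'   `rpm` assay).
#' @param groups factor or character vector assigning each sample to a
#'   group.
#' @param minRpm detection threshold in RPM.
#' @return Character vector of detected gene ids (row indices when the
#'   matrix has no row names).
#' @examples
#' m <- rbind(g1 = c(4, 5, 0, 0), g2 = c(4, 1, 2, 9))
#' colnames(m) <- paste0("s", 1:4)
#' filterDetected(m, groups = c("a", "a", "b", "b"))
#' @export
filterDetected <- function(rpm, groups, minRpm = 3) {
    m <- .assayOrMatrix(rpm, "rpm")
    groups <- as.factor(groups)
    if (length(groups) != ncol(m))
        stop("groups must have one entry per sample")
    if (any(table(groups) == 0))
        stop("empty group(s): ",
             paste(names(which(table(groups) == 0)), collapse = ", "))
    pass <- vapply(levels(groups), function(g) {
        sub <- m[, groups == g, drop = FALSE]
        apply(sub >= minRpm, 1, all)
    }, logical(nrow(m)))
    detected <- rowSums(as.matrix(pass)) > 0
    if (!is.null(rownames(m))) rownames(m)[detected] else which(detected)
}

#' Absolute quantification: mRNA molecules per cell
#'
#' Converts FPKM to absolute mRNA molecules per cell using the known
#' spike-in input amounts:
#' `molecules(gene, sample) = FPKM(gene) / nCells * sum(spike molecules) /
#' sum(spike FPKM in that sample)`. The spike rows are consumed by the
#' ratio and excluded from the returned biological matrix. The estimate is
#' invariant to any common rescaling of a sample's FPKM (the scale cancels
#' between numerator and spike sum) and linear in each gene's FPKM.
#'
#' @param fpkm (genes + spikes) x samples FPKM matrix, or a
#'   `SummarizedExperiment` with an assay named by `assay` and an `isSpike`
#'   row flag.
#' @param spikes spike-in reference: data.frame with `spike_id` and
#'   `molecules` columns, or a named numeric vector of molecules. Rows are
#'   matched to spike row names; spikes missing from the matrix are
#'   ignored.
#' @param cellsPerSample number of sorted cells per sample (single value or
#'   per-sample vector).
#' @param assay assay name when `fpkm` is a `SummarizedExperiment`.
#' @param spikePrefix spike row-name prefix fallback.
#' @return For a matrix input, the biological genes x samples matrix of
#'   molecules per cell; for a `SummarizedExperiment`, a new object
#'   restricted to biological genes with a `molecules` assay.
#' @examples
#' m <- rbind(geneA = 10, `ERCC-1` = 50)
#' colnames(m) <- "s1"
#' moleculesPerCell(m, spikes = c(`ERCC-1` = 100), cellsPerSample = 1)
#' @export
moleculesPerCell <- function(fpkm, spikes, cellsPerSample = 1000,
                             assay = "fpkm", spikePrefix = "ERCC-") {
    m <- .assayOrMatrix(fpkm, assay)
    spike <- .spikeFlag(fpkm, spikePrefix)
    if (!any(spike))
        stop("no spike-in rows found in the FPKM matrix")
    if (is.data.frame(spikes))
        spikes <- stats::setNames(spikes$molecules, spikes$spike_id)
    if (any(spikes <= 0)) stop("spike-in molecule counts must be positive")
    spikeNames <- rownames(m)[spike]
    if (!all(spikeNames %in% names(spikes)))
        stop("spike rows missing from the reference: ",
             paste(setdiff(spikeNames, names(spikes)), collapse = ", "))
    if (any(cellsPerSample <= 0)) stop("cellsPerSample must be positive")
    cellsPerSample <- rep_len(cellsPerSample, ncol(m))

    spikeFpkmSum <- colSums(m[spike, , drop = FALSE])
    bad <- which(spikeFpkmSum == 0)
    if (length(bad))
        stop("zero total spike-in FPKM in sample(s): ",
             paste(colnames(m)[bad] %||% bad, collapse = ", "))
    totalMolecules <- sum(spikes[spikeNames])
    factor <- totalMolecules / spikeFpkmSum / cellsPerSample
    mol <- sweep(m[!spike, , drop = FALSE], 2, factor, "*")
    if (is(fpkm, "SummarizedExperiment")) {
        out <- fpkm[!spike, ]
        SummarizedExperiment::assay(out, "molecules") <- mol
        out
    } else mol
}

#' Total mRNA content per sample
#'
#' Sum of absolute mRNA molecules per cell over all biological genes, the
#' per-sample quantity whose growth across divisions reflects the
#' division-linked increase in total transcript content.
#'
#' @param mol biological genes x samples matrix of molecules per cell, or a
#'   `SummarizedExperiment` with a `molecules` assay.
#' @return Named numeric vector, one total per sample.
#' @examples
#' totalMrnaContent(rbind(a = c(3, 1), b = c(4, 1)))
#' @export
totalMrnaContent <- function(mol) {
    m <- .assayOrMatrix(mol, "molecules")
    colSums(m)
}

#' Per-gene two-group differential test (Wilcoxon on log RPM)
#'
#' Assumption-light default test feeding [flagDEG()]: per gene, a two-sided
#' two-sample Wilcoxon rank-sum test on log2(RPM + 1), with the log2 fold
#' change of (mean + 1) expression between groups. Swappable: any table of
#' per-gene log2 fold changes and p-values can be passed to [flagDEG()].
#'
#' @param rpmA,rpmB genes x samples RPM matrices for the two groups (same
#'   genes, same order).
#' @return data.frame with `gene`, `log2FC` (A over B) and `p`.
#' @export
bulkDE <- function(rpmA, rpmB) {
    if (nrow(rpmA) != nrow(rpmB))
        stop("the two groups must share the same genes")
    n <- nrow(rpmA)
    p <- numeric(n)
    for (i in seq_len(n)) {
        a <- log2(rpmA[i, ] + 1); b <- log2(rpmB[i, ] + 1)
        p[i] <- if (stats::sd(c(a, b)) == 0) 1
        else suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    data.frame(gene = rownames(rpmA) %||% as.character(seq_len(n)),
               log2FC = log2((rowMeans(rpmA) + 1) / (rowMeans(rpmB) + 1)),
               p = p, stringsAsFactors = FALSE)
}

#' Flag differentially expressed genes with BH-FDR
#'
#' Applies the Benjamini-Hochberg step-up adjustment to per-gene p-values
#' and flags genes passing both the fold-change and FDR gates
#' (|log2FC| > `lfcThreshold` and FDR < `fdrThreshold`).
#'
#' @param stats data.frame with columns `log2FC` and `p` (optionally
#'   `gene`), e.g. from [bulkDE()].
#' @param lfcThreshold absolute log2 fold-change gate.
#' @param fdrThreshold BH-FDR gate.
#' @return The input with `fdr` and `significant` columns appended.
#' @examples
#' flagDEG(data.frame(log2FC = c(2, 0.5), p = c(0.001, 0.001)))
#' @export
flagDEG <- function(stats, lfcThreshold = 1, fdrThreshold = 0.05) {
    if (nrow(stats) == 0L) {
        stats$fdr <- numeric(0)
        stats$significant <- logical(0)
        return(stats)
    }
    if (!all(c("log2FC", "p") %in% colnames(stats)))
        stop("stats must have columns log2FC and p")
    if (any(is.na(stats$p)) || any(stats$p < 0 | stats$p > 1))
        stop("p-values must lie in [0, 1]")
    stats$fdr <- stats::p.adjust(stats$p, method = "BH")
    stats$significant <- abs(stats$log2FC) > lfcThreshold &
        stats$fdr < fdrThreshold
    stats
}
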