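#' Merge query cells with a reference panel on shared genes
#'
#' Restricts both matrices to the exact intersection of their gene ids and
#' binds the columns (query cells first, then reference replicates).
#'
#' @param query genes x cells matrix of query profiles.
#' @param reference genes x replicates matrix, or a
#'   `SummarizedExperiment` reference panel (its first assay is used).
#' @return List with `x` (combined matrix), `isReference` (logical per
#'   column) and `nGenes` (intersection size).
#' @examples
#' q <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("c1", "c2")))
#' r <- matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"), c("r1", "r2")))
#' mergeOnGenes(q, r)$nGenes
#' @export
mergeOnGenes <- function(query, reference) {
    ref <- if (is(reference, "SummarizedExperiment"))
        as.matrix(SummarizedExperiment::assay(reference, 1)) else
        as.matrix(reference)
    shared <- intersect(rownames(query), rownames(ref))
    if (length(shared) == 0L)
        stop("no genes shared between query and reference")
    x <- cbind(as.matrix(query)[shared, , drop = FALSE],
               ref[shared, , drop = FALSE])
    list(x = x,
         isReference = c(rep(FALSE, ncol(query)), rep(TRUE, ncol(ref))),
         nGenes = length(shared))
}

#' Quantile normalization of matrix columns
#'
#' Classic quantile normalization: sort each column, average across columns
#' at each rank, and map the averages back by rank, so that after
#' normalization the sorted values of every column are identical. Ties
#' within a column receive the mean of the values their tied ranks would
#' map to.
#'
#' @param x numeric matrix with at least two columns.
#' @return The normalized matrix.
#' @examples
#' quantileNormalizeColumns(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalizeColumns <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("quantile normalization needs >= 2 columns")
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
}

#' K-nearest-neighbor label transfer on a combined matrix
#'
#' Computes Euclidean distances from every query column to every reference
#' column of a (typically quantile-normalized) combined matrix and assigns
#' each query the plurality label of its `k` nearest references. Ties are
#' broken by the smaller mean distance among the tied labels, then by
#' lexicographic label order, so the assignment is deterministic.
#'
#' @param combined genes x columns matrix (query and reference columns).
#' @param isReference logical per column marking the reference columns.
#' @param labels label per reference column (in reference column order).
#' @param k number of neighbors; defaults to the smallest per-label
#'   replicate count in the panel.
#' @return `S4Vectors::DataFrame` with one row per query column: `label`,
#'   `voteFraction` (plurality vote share) and `nnDist` (distance to the
#'   nearest reference).
#' @export
knnAnnotate <- function(combined, isReference, labels, k = NULL) {
    ref <- combined[, isReference, drop = FALSE]
    qry <- combined[, !isReference, drop = FALSE]
    if (length(labels) != ncol(ref))
        stop("labels must have one entry per reference column")
    if (is.null(k)) k <- min(table(labels))
    if (k < 1) stop("k must be >= 1")
    if (k > ncol(ref))
        stop("k (", k, ") exceeds the number of reference columns (",
             ncol(ref), ")")
    ## squared Euclidean distances via the Gram expansion
    rr <- colSums(ref^2)
    qq <- colSums(qry^2)
    D2 <- outer(qq, rr, "+") - 2 * crossprod(qry, ref)
    D2[D2 < 0] <- 0
    out <- lapply(seq_len(ncol(qry)), function(i) {
        d <- sqrt(D2[i, ])
        ord <- order(d, seq_along(d))
        nn <- ord[seq_len(k)]
        votes <- table(labels[nn])
        top <- names(votes)[votes == max(votes)]
        if (length(top) > 1L) {
            meanDist <- vapply(top, function(l)
                mean(d[nn][labels[nn] == l]), numeric(1))
            top <- top[meanDist == min(meanDist)]
            top <- sort(top)[1]
        }
        list(label = top, vote = max(votes) / k, nn = min(d))
    })
    S4Vectors::DataFrame(
        label = vapply(out, `[[`, character(1), "label"),
        voteFraction = vapply(out, `[[`, numeric(1), "vote"),
        nnDist = vapply(out, `[[`, numeric(1), "nn"),
        row.names = colnames(qry))
}

#' Annotate single cells against a bulk reference panel
#'
#' The full reference-annotation bridge between single-cell and bulk data:
#' library-size normalizes the query cells (so they are comparable to
#' reads-per-million bulk profiles), merges query and panel on shared gene
#' ids, quantile normalizes the combined matrix, and transfers the
#' requested label track by k-nearest-neighbor voting with `k` defaulting
#' to the panel's replicate count.
#'
#' @param x a `SingleCellExperiment` (its `counts` assay is library-size
#'   normalized to counts per million) or a genes x cells matrix assumed
#'   already normalized.
#' @param panel reference panel from [simulateBulkReference()] or
#'   [readReferencePanel()]: a `SummarizedExperiment` whose `colData` has
#'   `label` and `track` columns.
#' @param track which label track to transfer (e.g. `"cellType"` or
#'   `"division"`).
#' @param k neighbors; default the smallest per-label replicate count.
#' @param excludeSpikes drop spike-in rows from the panel before merging.
#' @return `S4Vectors::DataFrame` as from [knnAnnotate()].
#' @export
annotateCells <- function(x, panel, track = "cellType", k = NULL,
                          excludeSpikes = TRUE) {
    qry <- if (is(x, "SingleCellExperiment")) {
        m <- .assayOrMatrix(x, "counts")
        sweep(m, 2, pmax(colSums(m), 1) / 1e6, "/")
    } else as.matrix(x)
    cd <- SummarizedExperiment::colData(panel)
    keep <- cd$track == track
    if (!any(keep)) stop("panel has no columns for track '", track, "'")
    sub <- panel[, keep]
    if (excludeSpikes) {
        spike <- .spikeFlag(sub)
        sub <- sub[!spike, ]
    }
    merged <- mergeOnGenes(qry, sub)
    qn <- quantileNormalizeColumns(merged$x)
    knnAnnotate(qn, merged$isReference,
                labels = SummarizedExperiment::colData(sub)$label, k = k)
}
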