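#' Single-cell quality-control filter
#'
#' Removes genes expressed (count > 0) in fewer than `minCellsPerGene`
#' cells and cells with fewer than `minUmiPerCell` total UMI. Both criteria
#' are evaluated on the input matrix in a single pass, so the kept sets do
#' not depend on removal order. Spike-in counts (in `altExp`) are not
#' counted toward a cell's UMI total and follow the cell subsetting.
#'
#' @param x a `SingleCellExperiment` with a raw `counts` assay, or a
#'   genes x cells count matrix.
#' @param minCellsPerGene minimum number of cells a gene must be expressed
#'   in to be retained.
#' @param minUmiPerCell minimum total UMI a cell must have to be retained.
#' @return The filtered object. For a `SingleCellExperiment`, a `qc` entry
#'   in `metadata` records how many genes/cells were removed and why.
#' @examples
#' m <- matrix(rpois(2000, 2), 40, 50,
#'             dimnames = list(paste0("g", 1:40), paste0("c", 1:50)))
#' dim(qcFilter(m, minCellsPerGene = 5, minUmiPerCell = 50))
#' @export
qcFilter <- function(x, minCellsPerGene = 10, minUmiPerCell = 1000) {
    m <- .assayOrMatrix(x, "counts")
    keepGene <- rowSums(m > 0) >= minCellsPerGene
    keepCell <- colSums(m) >= minUmiPerCell
    if (!any(keepCell))
        stop("QC removed every cell: ", ncol(m), " cells all below ",
             minUmiPerCell, " total UMI")
    report <- list(genesRemoved = sum(!keepGene),
                   cellsRemoved = sum(!keepCell),
                   minCellsPerGene = minCellsPerGene,
                   minUmiPerCell = minUmiPerCell)
    if (is(x, "SingleCellExperiment")) {
        out <- x[keepGene, keepCell]
        S4Vectors::metadata(out)$qc <- report
        out
    } else m[keepGene, keepCell, drop = FALSE]
}

#' Library-size normalization with square-root transform
#'
#' Scales every cell to the median library size of the input and applies an
#' element-wise square root — the variance-stabilizing normalization used
#' upstream of diffusion imputation. Preserves the within-cell rank order
#' of genes.
#'
#' @param x `SingleCellExperiment` with a `counts` assay, or a genes x
#'   cells count matrix.
#' @return For a matrix, the transformed matrix; for a
#'   `SingleCellExperiment`, the object with a `sqrtnorm` assay added.
#' @examples
#' libsizeSqrtTransform(matrix(c(4, 9), 2, 1))
#' @export
libsizeSqrtTransform <- function(x) {
    m <- .assayOrMatrix(x, "counts")
    lib <- colSums(m)
    bad <- which(lib == 0)
    if (length(bad))
        stop("cell(s) with zero library size: ",
             paste(colnames(m)[bad] %||% bad, collapse = ", "))
    target <- stats::median(lib)
    out <- sqrt(sweep(m, 2, lib / target, "/"))
    if (is(x, "SingleCellExperiment")) {
        SummarizedExperiment::assay(x, "sqrtnorm") <- out
        x
    } else out
}

#' Library-size normalization with log transform
#'
#' Scales every cell to 10^4 total counts and applies log(1 + x) — the
#' normalization used for dimensionality reduction and clustering.
#' Preserves the within-cell rank order of genes; the inverse transform
#' `expm1` recovers the scaled counts exactly.
#'
#' @inheritParams libsizeSqrtTransform
#' @return For a matrix, the transformed matrix; for a
#'   `SingleCellExperiment`, the object with a `lognorm` assay added.
#' @examples
#' logNormalize(matrix(c(0, 10), 2, 1))
#' @export
logNormalize <- function(x) {
    m <- .assayOrMatrix(x, "counts")
    lib <- colSums(m)
    bad <- which(lib == 0)
    if (length(bad))
        stop("cell(s) with zero library size: ",
             paste(colnames(m)[bad] %||% bad, collapse = ", "))
    out <- log1p(sweep(m, 2, lib / 1e4, "/"))
    if (is(x, "SingleCellExperiment")) {
        SummarizedExperiment::assay(x, "lognorm") <- out
        x
    } else out
}
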