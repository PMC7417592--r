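#' Build a Markov diffusion operator over cells
#'
#' Constructs the row-stochastic transition matrix used for diffusion
#' imputation: cells are embedded in the top `npcs` principal components of
#' the normalized matrix, a Euclidean k-nearest-neighbor kernel with
#' adaptive per-cell bandwidth (the distance to the `ka`-th neighbor) is
#' evaluated, symmetrized by addition, and row-normalized.
#'
#' @param x normalized genes x cells matrix (e.g. from
#'   [libsizeSqrtTransform()]), or a `SingleCellExperiment` with the assay
#'   named by `assay`.
#' @param k number of nearest neighbors in the affinity graph.
#' @param ka neighbor index setting the adaptive kernel bandwidth.
#' @param npcs number of principal components to embed in (capped at the
#'   matrix rank).
#' @param assay assay to use for a `SingleCellExperiment`.
#' @return A [DiffusionOperator-class].
#' @examples
#' m <- matrix(rnorm(500), 10, 50)
#' op <- buildDiffusionOperator(m, k = 10, ka = 4, npcs = 5)
#' range(rowSums(transitionMatrix(op)))
#' @export
buildDiffusionOperator <- function(x, k = 30, ka = 10, npcs = 20,
                                   assay = "sqrtnorm") {
    m <- .assayOrMatrix(x, assay)
    n <- ncol(m)
    if (k >= n)
        stop("k (", k, ") must be smaller than the number of cells (", n, ")")
    if (ka > k) stop("ka must not exceed k")
    cells <- t(m)
    npcs <- min(npcs, nrow(cells) - 1L, ncol(cells))
    if (npcs >= 1 && ncol(cells) > npcs) {
        pc <- stats::prcomp(cells, center = TRUE, scale. = FALSE)
        cells <- pc$x[, seq_len(min(npcs, ncol(pc$x))), drop = FALSE]
    }
    D <- as.matrix(stats::dist(cells))
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
        d <- D[i, ]
        ord <- order(d)
        nn <- ord[ord != i][seq_len(k)]
        sigma <- max(d[nn][ka], .Machine$double.eps)
        A[i, nn] <- exp(-(d[nn] / sigma)^2)
        A[i, i] <- 1
    }
    A <- A + t(A)
    P <- A / rowSums(A)
    dimnames(P) <- list(colnames(m), colnames(m))
    new("DiffusionOperator", transitions = P, k = as.integer(k),
        ka = as.integer(ka), npcs = as.integer(npcs))
}

#' Diffusion imputation of expression values
#'
#' Applies `t` steps of the Markov diffusion operator to the expression
#' matrix: `imputed = data %*% t(P^t)` column-wise, i.e. every cell becomes
#' a convex combination of its transcriptomic neighborhood. `t = 0` returns
#' the input unchanged; because the operator is row-stochastic, imputed
#' values stay inside each gene's observed range, and diffusion satisfies
#' the semigroup property `impute(x, t1 + t2) = impute(impute(x, t1), t2)`.
#'
#' @param x normalized genes x cells matrix (same cells the operator was
#'   built on), or a `SingleCellExperiment` carrying it in `assay`.
#' @param op a [DiffusionOperator-class] from [buildDiffusionOperator()].
#' @param t number of diffusion steps (non-negative integer).
#' @param assay input assay when `x` is a `SingleCellExperiment`.
#' @return For a matrix, the imputed matrix; for a `SingleCellExperiment`,
#'   the object with an `imputed` assay added.
#' @export
imputeExpression <- function(x, op, t = 3, assay = "sqrtnorm") {
    if (!is(op, "DiffusionOperator"))
        stop("op must be a DiffusionOperator")
    if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
    m <- .assayOrMatrix(x, assay)
    P <- op@transitions
    if (ncol(m) != nrow(P))
        stop("dimension mismatch: ", ncol(m), " cells in the matrix vs ",
             nrow(P), " in the operator")
    out <- m
    tp <- t(P)
    for (i in seq_len(t)) out <- out %*% tp
    dimnames(out) <- dimnames(m)
    if (is(x, "SingleCellExperiment")) {
        SummarizedExperiment::assay(x, "imputed") <- out
        x
    } else out
}
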