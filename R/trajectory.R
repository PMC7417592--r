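#' Principal-component reduction with a deterministic sign convention
#'
#' Top `numDim` principal components of the centered (log-normalized)
#' matrix. Each component's sign is fixed so that its largest-magnitude
#' gene loading is positive, making the embedding reproducible across
#' platforms.
#'
#' @param x log-normalized genes x cells matrix, or a
#'   `SingleCellExperiment` carrying it in `assay`.
#' @param numDim number of components to keep.
#' @param assay assay name for a `SingleCellExperiment`.
#' @return cells x `numDim` matrix of scores, with the per-component
#'   variances in `attr(, "sdev")` (all component standard deviations, for
#'   variance accounting).
#' @export
reduceDims <- function(x, numDim = 10, assay = "lognorm") {
    m <- .assayOrMatrix(x, assay)
    if (numDim > min(dim(m)))
        stop("numDim (", numDim, ") exceeds min(genes, cells)")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    keep <- seq_len(min(numDim, ncol(pc$x)))
    scores <- pc$x[, keep, drop = FALSE]
    for (j in keep) {
        load <- pc$rotation[, j]
        if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
    }
    rownames(scores) <- colnames(m)
    attr(scores, "sdev") <- pc$sdev
    scores
}

#' Deterministic 2D display embedding
#'
#' Projects a reduced embedding to two display dimensions. The projection
#' is the two leading principal directions of the embedding (a linear,
#' fully deterministic layout used in place of a stochastic t-SNE), with
#' the same sign convention as [reduceDims()]. A neighbor-preservation
#' score — the mean fraction of each cell's `ceiling(perplexity)` nearest
#' neighbors in the input space retained among its 2D neighbors — is
#' attached so the quality of the flattening is visible.
#'
#' @param embedding cells x d matrix (e.g. from [reduceDims()]).
#' @param perplexity neighborhood size used for the preservation score.
#' @param seed accepted for interface stability; the embedding is
#'   deterministic and does not consume randomness.
#' @return cells x 2 matrix with attribute `neighborPreservation`.
#' @export
embed2d <- function(embedding, perplexity = 30, seed = 1) {
    embedding <- as.matrix(embedding)
    n <- nrow(embedding)
    if (ncol(embedding) > 2L) {
        pc <- stats::prcomp(embedding, center = TRUE, scale. = FALSE)
        out <- pc$x[, 1:2, drop = FALSE]
        for (j in 1:2) {
            load <- pc$rotation[, j]
            if (load[which.max(abs(load))] < 0) out[, j] <- -out[, j]
        }
    } else {
        out <- embedding
        if (ncol(out) < 2L) out <- cbind(out, 0)
    }
    rownames(out) <- rownames(embedding)
    colnames(out) <- c("dim1", "dim2")
    nn <- min(ceiling(perplexity), n - 1L)
    if (nn >= 1L && n >= 3L) {
        dFull <- as.matrix(stats::dist(embedding))
        d2d <- as.matrix(stats::dist(out))
        keep <- vapply(seq_len(n), function(i) {
            a <- order(dFull[i, -i])[seq_len(nn)]
            b <- order(d2d[i, -i])[seq_len(nn)]
            length(intersect(a, b)) / nn
        }, numeric(1))
        attr(out, "neighborPreservation") <- mean(keep)
    } else attr(out, "neighborPreservation") <- NA_real_
    out
}

#' Density-peak clustering
#'
#' Clusters cells with the density-peak rule: local density `rho` is the
#' number of cells within a kernel distance `dc` (chosen so the average
#' neighborhood holds about `neighborFraction` of the data), `delta` is the
#' distance to the nearest higher-density cell (the global density maximum
#' takes the maximum pairwise distance), cluster centers are the cells
#' exceeding both the `rhoQuantile` and `deltaQuantile` thresholds — by
#' default denser than the median cell and more isolated than 95% of
#' cells, so that real but small modes are not crowded out by the largest
#' ones — and
#' every remaining cell joins the cluster of its nearest higher-density
#' neighbor, processed in decreasing density order. When no cell clears
#' both thresholds (e.g. all cells identical) a single cluster centered on
#' the density maximum is returned.
#'
#' Clusters seeded by spurious local density fluctuations inside one mode
#' are removed by a saddle-density merge: two clusters are merged when the
#' density at their border (the largest `min(rho_i, rho_j)` over cell
#' pairs within `dc` of each other across the boundary) reaches
#' `mergeFactor` times the density of the weaker cluster's center — a
#' genuine pair of modes is separated by a low-density gap, a fluctuation
#' pair is not.
#'
#' @param embedding cells x d reduced coordinates.
#' @param neighborFraction target mean neighborhood fraction defining the
#'   kernel distance `dc`.
#' @param rhoQuantile,deltaQuantile quantiles of `rho` and `delta` a center
#'   must exceed.
#' @param mergeFactor saddle-to-peak density ratio above which two
#'   clusters are considered one mode (0 disables merging).
#' @return A [ClusterModel-class].
#' @export
clusterDensityPeak <- function(embedding, neighborFraction = 0.02,
                               rhoQuantile = 0.5, deltaQuantile = 0.95,
                               mergeFactor = 0.5) {
    embedding <- as.matrix(embedding)
    n <- nrow(embedding)
    if (n < 10L) stop("density-peak clustering needs at least 10 cells")
    D <- as.matrix(stats::dist(embedding))
    off <- D[upper.tri(D)]
    dc <- stats::quantile(off, neighborFraction, names = FALSE)
    if (dc == 0) dc <- .Machine$double.eps
    rho <- rowSums(D < dc) - 1
    ## density order; ties broken by index for determinism
    ord <- order(-rho, seq_len(n))
    delta <- numeric(n)
    higher <- integer(n)          # nearest cell earlier in density order
    maxD <- max(D)
    delta[ord[1]] <- maxD
    higher[ord[1]] <- ord[1]
    for (r in 2:n) {
        i <- ord[r]
        prev <- ord[seq_len(r - 1L)]
        j <- prev[which.min(D[i, prev])]
        delta[i] <- D[i, j]
        higher[i] <- j
    }
    rhoThr <- stats::quantile(rho, rhoQuantile, names = FALSE)
    deltaThr <- stats::quantile(delta, deltaQuantile, names = FALSE)
    centers <- which(rho > rhoThr & delta > deltaThr)
    if (length(centers) == 0L) centers <- ord[1]
    cluster <- integer(n)
    cluster[centers] <- seq_along(centers)
    for (r in seq_len(n)) {
        i <- ord[r]
        if (cluster[i] == 0L) cluster[i] <- cluster[higher[i]]
    }
    if (mergeFactor > 0 && length(centers) > 1L) {
        k <- length(centers)
        saddle <- matrix(0, k, k)
        near <- which(D < dc & row(D) < col(D), arr.ind = TRUE)
        if (nrow(near)) {
            ca <- cluster[near[, 1]]; cb <- cluster[near[, 2]]
            cross <- ca != cb
            if (any(cross)) {
                lo <- pmin(rho[near[cross, 1]], rho[near[cross, 2]])
                for (idx in seq_along(lo)) {
                    a <- ca[cross][idx]; b <- cb[cross][idx]
                    saddle[a, b] <- saddle[b, a] <-
                        max(saddle[a, b], lo[idx])
                }
            }
        }
        peak <- rho[centers]
        join <- saddle >= mergeFactor * outer(peak, peak, pmin) &
            upper.tri(saddle)
        if (any(join)) {
            g <- igraph::graph_from_edgelist(
                cbind(row(join)[join], col(join)[join]), directed = FALSE)
            g <- igraph::add_vertices(
                g, max(0L, k - igraph::vcount(g)))
            comp <- igraph::components(g)$membership
            cluster <- comp[cluster]
            keep <- vapply(seq_len(max(comp)), function(cm) {
                cand <- centers[comp == cm]
                cand[which.max(rho[cand])]
            }, integer(1))
            centers <- keep
            ## renumber so cluster ids are 1..k in center order
            relabel <- match(cluster, sort(unique(cluster)))
            cluster <- relabel
        }
    }
    new("ClusterModel", cluster = as.integer(cluster),
        rho = as.numeric(rho),
        delta = delta, centers = as.integer(centers), dc = dc,
        rhoThreshold = rhoThr, deltaThreshold = deltaThr)
}

#' Select trajectory ordering genes
#'
#' Ranks genes by their across-cluster association (Kruskal-Wallis test on
#' normalized expression), adjusts with BH, and returns the top `nTop`
#' genes by ascending q-value with p-value and then the Kruskal-Wallis
#' statistic (larger first) and gene id as tie-breakers. Genes constant
#' across all cells take p = 1 by convention and are never selected before
#' varying genes.
#'
#' @param x normalized genes x cells matrix (or `SingleCellExperiment`
#'   with the assay in `assay`).
#' @param clusters a [ClusterModel-class] or an integer/factor vector of
#'   cluster ids per cell (>= 2 distinct clusters required).
#' @param nTop number of genes to return; when it exceeds the gene count
#'   all genes are returned with a warning.
#' @param assay assay name for a `SingleCellExperiment`.
#' @return Character vector of selected genes, with the full per-gene
#'   table (gene, statistic, p, q) in `attr(, "stats")`.
#' @export
selectOrderingGenes <- function(x, clusters, nTop = 1000,
                                assay = "lognorm") {
    m <- .assayOrMatrix(x, assay)
    cl <- if (is(clusters, "ClusterModel")) clusters@cluster else clusters
    cl <- as.factor(cl)
    if (nlevels(cl) < 2L)
        stop("ordering-gene selection needs at least 2 clusters")
    if (length(cl) != ncol(m))
        stop("clusters must have one entry per cell")
    res <- t(vapply(seq_len(nrow(m)), function(i) {
        v <- m[i, ]
        if (max(v) == min(v)) return(c(stat = 0, p = 1))
        kw <- stats::kruskal.test(v, cl)
        c(stat = unname(kw$statistic), p = kw$p.value)
    }, numeric(2)))
    genes <- rownames(m) %||% as.character(seq_len(nrow(m)))
    tab <- data.frame(gene = genes, stat = res[, 1], p = res[, 2],
                      q = stats::p.adjust(res[, 2], method = "BH"),
                      stringsAsFactors = FALSE)
    if (nTop > nrow(tab)) {
        warning("nTop (", nTop, ") exceeds the number of genes (",
                nrow(tab), "); returning all genes")
        nTop <- nrow(tab)
    }
    ord <- order(tab$q, tab$p, -tab$stat, tab$gene)
    sel <- tab$gene[ord][seq_len(nTop)]
    attr(sel, "stats") <- tab
    sel
}

## Edge segments of a tree: edges merged through nodes of degree 2 form one
## branch-point-free segment.
.edgeSegments <- function(edges, nNodes) {
    nE <- nrow(edges)
    if (nE == 0L) return(integer(0))
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nNodes)
    seg <- integer(nE)
    current <- 0L
    incident <- lapply(seq_len(nNodes), function(v)
        which(edges[, 1] == v | edges[, 2] == v))
    for (e in seq_len(nE)) {
        if (seg[e] != 0L) next
        current <- current + 1L
        queue <- e
        while (length(queue)) {
            f <- queue[1]; queue <- queue[-1]
            if (seg[f] != 0L) next
            seg[f] <- current
            for (v in edges[f, ]) {
                if (deg[v] == 2L) {
                    others <- setdiff(incident[[v]], f)
                    queue <- c(queue, others[seg[others] == 0L])
                }
            }
        }
    }
    seg
}

#' Fit a branching principal tree and order cells along it
#'
#' Builds a minimum spanning tree over the cluster centroids in the reduced
#' space, projects every cell onto the nearest point of an edge incident to
#' its cluster's node, and sets pseudotime to the geodesic distance from
#' the root along the tree (plus the projection offset). Branch points are
#' tree nodes of degree >= 3; branches are the maximal branch-point-free
#' segments of the tree. Pseudotime is monotone non-decreasing along every
#' root-to-leaf walk by construction.
#'
#' @param embedding cells x d reduced coordinates (typically
#'   [reduceDims()] of the data restricted to ordering genes).
#' @param clusters a [ClusterModel-class] or integer cluster ids per cell.
#' @param root root cluster id; alternatively supply `rootLabels`.
#' @param rootLabels per-cell labels (e.g. cell-type annotations); the
#'   cluster with the highest fraction of `rootLabel` cells becomes the
#'   root.
#' @param rootLabel label defining the root population (default the naive
#'   B-cell label `"nB"`).
#' @return A [TrajectoryModel-class].
#' @export
fitPrincipalTree <- function(embedding, clusters, root = NULL,
                             rootLabels = NULL, rootLabel = "nB") {
    embedding <- as.matrix(embedding)
    cl <- if (is(clusters, "ClusterModel")) clusters@cluster else
        as.integer(as.factor(clusters))
    if (length(cl) != nrow(embedding))
        stop("clusters must have one entry per cell")
    nClust <- max(cl)
    centroids <- t(vapply(seq_len(nClust), function(g)
        colMeans(embedding[cl == g, , drop = FALSE]),
        numeric(ncol(embedding))))

    if (is.null(root)) {
        if (!is.null(rootLabels)) {
            frac <- vapply(seq_len(nClust), function(g)
                mean(rootLabels[cl == g] == rootLabel), numeric(1))
            root <- which.max(frac)
        } else root <- 1L
    }
    root <- as.integer(root)
    if (root < 1L || root > nClust) stop("root must be a cluster id")

    if (nClust == 1L) {
        return(new("TrajectoryModel", embedding = embedding, cluster = cl,
                   centroids = centroids,
                   edges = matrix(integer(0), 0, 2),
                   edgeLengths = numeric(0), root = root,
                   pseudotime = rep(0, nrow(embedding)),
                   cellEdge = rep(NA_integer_, nrow(embedding)),
                   cellOffset = rep(0, nrow(embedding)),
                   branch = rep(1L, nrow(embedding)),
                   branchPoints = integer(0)))
    }

    Dc <- as.matrix(stats::dist(centroids))
    g <- igraph::graph_from_adjacency_matrix(Dc, mode = "undirected",
                                             weighted = TRUE)
    tree <- igraph::mst(g)
    el <- igraph::as_edgelist(tree, names = FALSE)
    storage.mode(el) <- "integer"
    lens <- vapply(seq_len(nrow(el)), function(e)
        Dc[el[e, 1], el[e, 2]], numeric(1))
    nodeDist <- igraph::distances(tree, v = root,
                                  weights = igraph::E(tree)$weight)[1, ]

    deg <- tabulate(c(el[, 1], el[, 2]), nbins = nClust)
    branchPoints <- which(deg >= 3L)
    seg <- .edgeSegments(el, nClust)

    n <- nrow(embedding)
    pt <- numeric(n); cellEdge <- integer(n); cellOffset <- numeric(n)
    incident <- lapply(seq_len(nClust), function(v)
        which(el[, 1] == v | el[, 2] == v))
    for (i in seq_len(n)) {
        edgesHere <- incident[[cl[i]]]
        best <- Inf; bestE <- NA_integer_; bestT <- 0; bestPt <- 0
        xi <- embedding[i, ]
        for (e in edgesHere) {
            a <- el[e, 1]; b <- el[e, 2]
            pa <- centroids[a, ]; pb <- centroids[b, ]
            len2 <- sum((pb - pa)^2)
            tt <- if (len2 == 0) 0 else
                min(1, max(0, sum((xi - pa) * (pb - pa)) / len2))
            proj <- pa + tt * (pb - pa)
            resid <- sum((xi - proj)^2)
            if (resid < best) {
                best <- resid; bestE <- e; bestT <- tt
                bestPt <- if (nodeDist[b] >= nodeDist[a])
                    nodeDist[a] + tt * lens[e]
                else nodeDist[b] + (1 - tt) * lens[e]
            }
        }
        pt[i] <- bestPt; cellEdge[i] <- bestE; cellOffset[i] <- bestT
    }
    branch <- seg[cellEdge]
    new("TrajectoryModel", embedding = embedding, cluster = cl,
        centroids = centroids, edges = el, edgeLengths = lens,
        root = root, pseudotime = pt, cellEdge = cellEdge,
        cellOffset = cellOffset, branch = as.integer(branch),
        branchPoints = as.integer(branchPoints))
}

#' Branch assignment from a fitted trajectory
#'
#' Recomputes the per-cell branch id from the tree structure: branch
#' points are nodes of degree >= 3 and a branch is a maximal
#' branch-point-free segment; each cell belongs to the segment of the edge
#' it projects onto. A path tree yields one branch; a Y-shaped tree three.
#'
#' @param model a [TrajectoryModel-class].
#' @return Integer branch id per cell.
#' @export
assignBranches <- function(model) {
    if (!is(model, "TrajectoryModel")) stop("model must be a TrajectoryModel")
    if (nrow(model@edges) == 0L)
        return(rep(1L, nrow(model@embedding)))
    seg <- .edgeSegments(model@edges, nrow(model@centroids))
    as.integer(seg[model@cellEdge])
}
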