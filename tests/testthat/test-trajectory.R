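test_that("PCA reduction honors rank, equivariance and the spectral identity", {
    set.seed(1)
    ## rank-1 data: one component carries essentially all variance
    u <- rnorm(20); v <- rnorm(40)
    rank1 <- outer(u, v) + matrix(rnorm(800, sd = 1e-4), 20, 40)
    emb <- reduceDims(rank1, numDim = 3)
    sdev <- attr(emb, "sdev")
    expect_gt(sdev[1]^2 / sum(sdev^2), 0.999)

    m <- matrix(rnorm(30 * 25), 30, 25,
                dimnames = list(paste0("g", 1:30), paste0("c", 1:25)))
    emb <- reduceDims(m, numDim = 5)
    perm <- sample(25)
    embPerm <- reduceDims(m[, perm], numDim = 5)
    expect_equal(embPerm, emb[perm, ], tolerance = 1e-9,
                 ignore_attr = TRUE)

    ## reconstruction error equals the discarded eigenvalue mass
    k <- 5
    X <- scale(t(m), scale = FALSE)
    sv <- svd(X)
    recon <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
    errF <- sum((X - recon)^2)
    discarded <- sum(attr(emb, "sdev")[-(1:k)]^2) * (nrow(X) - 1)
    expect_equal(errF, discarded, tolerance = 1e-6)

    expect_error(reduceDims(m, numDim = 40), "exceeds")
})

test_that("the 2D embedding is deterministic and separates blobs", {
    set.seed(2)
    blobs <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
                   matrix(rnorm(100, 10, 0.5), 50, 2))
    emb <- cbind(blobs, matrix(rnorm(100 * 3, sd = 0.1), 100, 3))
    a <- embed2d(emb)
    b <- embed2d(emb)
    expect_identical(a, b)
    cent1 <- colMeans(a[1:50, ]); cent2 <- colMeans(a[51:100, ])
    spread <- max(apply(a[1:50, ], 2, sd), apply(a[51:100, ], 2, sd))
    expect_gt(sqrt(sum((cent1 - cent2)^2)), spread)
    expect_true(attr(a, "neighborPreservation") > 0.5)

    tiny <- matrix(rnorm(9), 3, 3)
    expect_silent(embed2d(tiny))
})

test_that("density-peak clustering resolves blob structure", {
    set.seed(42)
    one <- matrix(rnorm(1000, sd = 0.5), ncol = 2)
    expect_identical(length(unique(clusterIds(clusterDensityPeak(one)))), 1L)

    three <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
                   matrix(rnorm(200, 8, 0.5), ncol = 2),
                   cbind(rnorm(100, 0, 0.5), rnorm(100, 8, 0.5)))
    cl <- clusterDensityPeak(three)
    ids <- clusterIds(cl)
    expect_identical(length(unique(ids)), 3L)
    truthB <- rep(1:3, each = 100)
    purity <- vapply(1:3, function(g)
        max(table(ids[truthB == g])) / 100, numeric(1))
    expect_true(all(purity >= 0.95))

    ## delta of the global density maximum is the max pairwise distance
    D <- as.matrix(dist(three))
    expect_equal(max(cl@delta), max(D))

    expect_error(clusterDensityPeak(matrix(0, 5, 2)), "at least 10")
    ident <- clusterDensityPeak(matrix(1, 20, 2))
    expect_identical(length(unique(clusterIds(ident))), 1L)
})

test_that("ordering genes are ranked by cluster association", {
    set.seed(3)
    n <- 60
    cl <- rep(1:3, each = 20)
    m <- matrix(rnorm(20 * n), 20, n)
    m[5, ] <- ifelse(cl == 2, 10, 0) + rnorm(n, sd = 0.1)  # separated
    m[9, ] <- 7                                            # constant
    rownames(m) <- paste0("g", 1:20)
    sel <- selectOrderingGenes(m, cl, nTop = 3)
    expect_true("g5" %in% sel)
    stats <- attr(sel, "stats")
    expect_identical(stats$p[stats$gene == "g9"], 1)
    expect_false("g9" %in% sel)

    ## Kruskal-Wallis oracle on a small case without ties
    v <- m[5, ]
    r <- rank(v)
    kwHand <- 12 / (n * (n + 1)) *
        sum(tapply(r, cl, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
    expect_equal(stats$stat[stats$gene == "g5"], kwHand, tolerance = 1e-9)

    expect_warning(sel2 <- selectOrderingGenes(m, cl, nTop = 100),
                   "exceeds")
    expect_identical(length(sel2), 20L)
    expect_error(selectOrderingGenes(m, rep(1, n)), "2 clusters")
})

test_that("a 1-D gradient yields a path with faithful pseudotime", {
    set.seed(4)
    pos <- sort(runif(200, 0, 10))
    emb <- cbind(pos, rnorm(200, sd = 0.05))
    cl <- as.integer(cut(pos, breaks = seq(0, 10, by = 2),
                         include.lowest = TRUE))
    model <- fitPrincipalTree(emb, cl, root = 1L)
    expect_identical(length(branchPoints(model)), 0L)
    expect_identical(length(unique(model@branch)), 1L)
    expect_gte(cor(pseudotime(model), pos, method = "spearman"), 0.95)
    ## a cell at the root centroid has pseudotime 0
    rootCent <- model@centroids[model@root, ]
    emb2 <- rbind(emb, rootCent)
    model2 <- fitPrincipalTree(emb2, c(cl, 1L), root = 1L)
    expect_equal(pseudotime(model2)[201], 0, tolerance = 1e-12)
    expect_equal(min(pseudotime(model2)), 0, tolerance = 1e-12)
})

test_that("Y and star topologies give the expected branches", {
    set.seed(5)
    arm <- function(dir, n = 120) {
        t <- runif(n, 0, 4)
        cbind(t * dir[1], t * dir[2]) + matrix(rnorm(2 * n, sd = 0.05),
                                               n, 2)
    }
    ## Y: stem down, two arms up; clusters along each part
    stem <- arm(c(0, -1)); armA <- arm(c(-1, 1)); armB <- arm(c(1, 1))
    emb <- rbind(stem, armA, armB)
    seg <- function(x) 1L + as.integer(sqrt(rowSums(x^2)) > 2)
    cl <- c(seg(stem), 2L + seg(armA), 4L + seg(armB))
    model <- fitPrincipalTree(emb, cl, root = 2L)
    expect_identical(length(branchPoints(model)), 1L)
    expect_identical(length(unique(assignBranches(model))), 3L)

    ## star with 4 leaves around a hub
    hub <- matrix(rnorm(60, sd = 0.05), 30, 2)
    leaves <- do.call(rbind, lapply(list(c(3, 0), c(-3, 0), c(0, 3),
                                         c(0, -3)), function(cc)
        matrix(rnorm(60, sd = 0.05), 30, 2) + rep(cc, each = 30)))
    embS <- rbind(hub, leaves)
    clS <- c(rep(1L, 30), rep(2:5, each = 30))
    star <- fitPrincipalTree(embS, clS, root = 2L)
    expect_identical(length(branchPoints(star)), 1L)
    expect_identical(star@branchPoints, 1L)
    expect_identical(length(unique(assignBranches(star))), 4L)
})

test_that("pseudotime is monotone along every root-to-leaf walk", {
    set.seed(6)
    pos <- sort(runif(150, 0, 9))
    emb <- cbind(pos, rnorm(150, sd = 0.05))
    cl <- as.integer(cut(pos, breaks = seq(0, 9, by = 3),
                         include.lowest = TRUE))
    model <- fitPrincipalTree(emb, cl, root = 1L)
    ## cluster-mean pseudotime must increase with distance from the root
    mp <- tapply(pseudotime(model), clusterIds(model), mean)
    expect_true(all(diff(mp) > 0))

    ## single-cluster degenerate case: flat trajectory without branches
    flat <- fitPrincipalTree(emb, rep(1L, 150), root = 1L)
    expect_identical(unique(pseudotime(flat)), 0)
    expect_identical(length(branchPoints(flat)), 0L)
    expect_identical(unique(assignBranches(flat)), 1L)
})

test_that("the root can be chosen from reference annotations", {
    set.seed(7)
    emb <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
                 matrix(rnorm(60, 5, 0.2), 30, 2))
    cl <- rep(1:2, each = 30)
    labels <- c(rep("nB", 25), rep("actB", 35))
    model <- fitPrincipalTree(emb, cl, rootLabels = labels)
    expect_identical(model@root, 1L)
})
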