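test_that("gene ranking places significant genes at the extremes", {
    r <- rankGenes(p = c(a = 0, b = 1, c = 0.5), fc = c(2, 1, -1))
    expect_identical(names(r)[1], "a")
    expect_identical(unname(r["a"]), 1)
    expect_identical(unname(r["b"]), 0)
    expect_lt(r["c"], 0)

    set.seed(1)
    p <- runif(10); fc <- rnorm(10)
    genes <- paste0("g", 1:10)
    r <- rankGenes(p, fc, genes)
    score <- sign(fc) * (1 - p)
    oracle <- genes[order(-score, -abs(fc), genes)]
    expect_identical(names(r), oracle)

    lit <- rankGenes(p, fc, genes, mode = "literal")
    scoreL <- sign(fc) * p
    expect_identical(names(lit), genes[order(-scoreL, -abs(fc), genes)])

    expect_warning(r2 <- rankGenes(c(0.1, 0.2), c(1, NA),
                                   genes = c("a", "b")), "dropped")
    expect_identical(names(r2), "a")
    expect_error(rankGenes(c(0.5, 2), c(1, 1)), "\\[0, 1\\]")
})

test_that("a single top-ranked hit attains the maximal enrichment score", {
    ranked <- rankGenes(p = seq(0.01, 0.9, length.out = 20),
                        fc = rep(1, 20), genes = paste0("g", 1:20))
    res <- gseaPreranked(ranked, names(ranked)[1], nPerm = 100, seed = 1)
    expect_equal(enrichmentScore(res), 1)
    expect_identical(leadingEdge(res), names(ranked)[1])
})

test_that("the enrichment score matches the running-sum oracle", {
    set.seed(2)
    for (rep in 1:30) {
        N <- sample(30:120, 1)
        scores <- sort(rnorm(N), decreasing = TRUE)
        names(scores) <- paste0("g", 1:N)
        size <- sample(3:15, 1)
        set <- sample(names(scores), size)
        res <- gseaPreranked(scores, set, nPerm = 10, seed = rep)
        expect_equal(enrichmentScore(res),
                     gseaOracle(scores, names(scores) %in% set),
                     tolerance = 1e-12)
    }
})

test_that("the score agrees with an independent implementation", {
    skip_if_not_installed("fgsea")
    set.seed(3)
    N <- 100
    scores <- sort(rnorm(N, 1), decreasing = TRUE)  # shifted: clear sign
    names(scores) <- paste0("g", 1:N)
    set <- names(scores)[c(2, 5, 9, 12, 20)]
    ours <- enrichmentScore(gseaPreranked(scores, set, nPerm = 10))
    theirs <- fgsea::calcGseaStat(scores, which(names(scores) %in% set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("reversing a symmetric ranked list flips the score sign", {
    set.seed(4)
    half <- sort(runif(30, 0.1, 1), decreasing = TRUE)
    scores <- c(half, -rev(half))            # symmetric about zero
    names(scores) <- paste0("g", 1:60)
    set <- paste0("g", c(2, 4, 7, 11, 13))
    fwd <- gseaPreranked(scores, set, nPerm = 10, seed = 1)
    revScores <- rev(-scores)
    revd <- gseaPreranked(revScores, set, nPerm = 10, seed = 1)
    expect_equal(enrichmentScore(revd), -enrichmentScore(fwd),
                 tolerance = 1e-12)
})

test_that("permutation p-values respect the +1 floor", {
    set.seed(5)
    scores <- sort(rnorm(200, 2), decreasing = TRUE)
    names(scores) <- paste0("g", 1:200)
    res <- gseaPreranked(scores, names(scores)[1:10], nPerm = 200,
                         seed = 2)
    expect_gte(permutationP(res), 1 / 201)
    expect_lte(permutationP(res), 1)
    expect_error(gseaPreranked(scores, "absent"), "no gene")
})

test_that("the leading edge contains the hits before the extremum", {
    scores <- c(5, 4, 3, -0.1, -0.2, -0.5, -1, -2)
    names(scores) <- paste0("g", 1:8)
    ## whole set in the top half: leading edge = whole set
    res <- gseaPreranked(scores, c("g1", "g2", "g3"), nPerm = 10)
    expect_setequal(leadingEdge(res), c("g1", "g2", "g3"))

    ## oracle comparison on random instances (positive-score side)
    set.seed(6)
    for (rep in 1:10) {
        N <- 50
        sc <- sort(rnorm(N), decreasing = TRUE)
        names(sc) <- paste0("g", 1:N)
        set <- sample(names(sc), 8)
        res <- gseaPreranked(sc, set, nPerm = 10, seed = rep)
        isHit <- names(sc) %in% set
        w <- abs(sc); w[!isHit] <- 0
        inc <- ifelse(isHit, w / sum(w[isHit]), 0)
        run <- cumsum(inc - ifelse(isHit, 0, 1 / (N - 8)))
        es <- enrichmentScore(res)
        le <- if (es > 0) names(sc)[isHit & seq_len(N) <= which.max(run)]
              else names(sc)[isHit & seq_len(N) >= which.min(run)]
        expect_setequal(leadingEdge(res), le)
    }
})

test_that("activity scores follow the cube-of-mean contract", {
    m <- rbind(a = c(0, 2, 1), b = c(0, 2, 3))
    colnames(m) <- paste0("c", 1:3)
    s <- activityScore(m, c("a", "b"))
    expect_equal(unname(s), c(0, 8, 8))
    one <- activityScore(m["a", , drop = FALSE], "a")
    expect_equal(unname(one), c(0, 8, 1))

    moc <- activityScore(m, c("a", "b"), mode = "mean-of-cubes")
    expect_equal(unname(moc), c(0, 8, 14))

    set.seed(7)
    big <- matrix(rexp(300), 15, 20,
                  dimnames = list(paste0("g", 1:15), NULL))
    sc <- activityScore(big, paste0("g", 1:6))
    plain <- colMeans(big[1:6, ])
    expect_identical(order(sc), order(plain))
    expect_error(activityScore(big, "missing"), "none of the genes")
})

test_that("pseudotime profiles normalize every gene to its peak bin", {
    set.seed(8)
    n <- 100
    pt <- runif(n)
    m <- rbind(const = rep(2, n),
               mono = 5 * pt + 0.1,
               zero = rep(0, n))
    prof <- pseudotimeProfile(m, pt, nBins = 10)
    expect_true(all(prof["const", ] == 1))
    expect_identical(unname(prof["mono", 10]), 1)
    expect_true(all(prof["zero", ] == 0))
    expect_true(all(apply(prof[c("const", "mono"), ], 1, max) == 1))
    expect_error(pseudotimeProfile(m, pt, nBins = 200), "exceeds")
    expect_error(pseudotimeProfile(m, pt[-1]), "one entry per cell")
})
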