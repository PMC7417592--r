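test_that("perfect target recovery scores maximal activity", {
    n <- 200
    expr <- matrix(0, n, 1, dimnames = list(paste0("g", 1:n), "c1"))
    expr[, 1] <- seq(n, 1)            # g1 highest ... gn lowest
    reg <- data.frame(factor = "f", target = paste0("g", 1:5),
                      motif_class = "other")
    act <- scoreRegulons(expr, reg, topFraction = 0.05)
    expect_equal(unname(act["f", "c1"]), 1)
})

test_that("rank-auc matches the explicit step-sum oracle", {
    set.seed(1)
    for (rep in 1:20) {
        n <- sample(50:200, 1)
        expr <- matrix(rnorm(n * 3), n, 3,
                       dimnames = list(paste0("g", seq_len(n)),
                                       paste0("c", 1:3)))
        tIdx <- sample(n, sample(4:12, 1))
        reg <- data.frame(factor = "f",
                          target = rownames(expr)[tIdx],
                          motif_class = "other")
        act <- scoreRegulons(expr, reg, topFraction = 0.1)
        for (j in 1:3)
            expect_equal(unname(act["f", j]),
                         rankAucOracle(expr[, j], tIdx, 0.1),
                         tolerance = 1e-12)
    }
})

test_that("random targets score near the analytic baseline", {
    set.seed(2)
    n <- 400; nCells <- 500; tSize <- 20
    expr <- matrix(rnorm(n * nCells), n, nCells,
                   dimnames = list(paste0("g", 1:n), NULL))
    reg <- data.frame(factor = "f",
                      target = paste0("g", sample(n, tSize)),
                      motif_class = "other")
    act <- scoreRegulons(expr, reg, topFraction = 0.05)
    nTop <- round(0.05 * n)
    baseline <- tSize * nTop * (nTop + 1) / (2 * n) /
        sum(pmin(seq_len(nTop), tSize))
    se <- sd(act["f", ]) / sqrt(nCells)
    expect_lt(abs(mean(act["f", ]) - baseline), 3 * se)
})

test_that("rank-auc is invariant to per-cell monotone transforms", {
    set.seed(3)
    expr <- matrix(rexp(100 * 5), 100, 5,
                   dimnames = list(paste0("g", 1:100), paste0("c", 1:5)))
    reg <- data.frame(factor = "f", target = paste0("g", 1:8),
                      motif_class = "other")
    a <- scoreRegulons(expr, reg)
    b <- scoreRegulons(expr^2, reg)       # monotone on positives
    cc <- scoreRegulons(log1p(expr), reg)
    expect_equal(a, b)
    expect_equal(a, cc)
})

test_that("factors without expressed targets are dropped with a warning", {
    expr <- matrix(rnorm(50), 10, 5,
                   dimnames = list(paste0("g", 1:10), NULL))
    reg <- rbind(data.frame(factor = "ok", target = c("g1", "g2"),
                            motif_class = "other"),
                 data.frame(factor = "gone", target = c("x1", "x2"),
                            motif_class = "other"))
    expect_warning(act <- scoreRegulons(expr, reg), "gone")
    expect_identical(rownames(act), "ok")
    expect_error(suppressWarnings(
        scoreRegulons(expr, reg[reg$factor == "gone", ])), "no regulon")
})

test_that("mean-cubed mode delegates to the activity score", {
    set.seed(4)
    expr <- matrix(rexp(200), 20, 10,
                   dimnames = list(paste0("g", 1:20), NULL))
    reg <- data.frame(factor = "f", target = paste0("g", 1:6),
                      motif_class = "other")
    act <- scoreRegulons(expr, reg, mode = "mean-cubed")
    expect_equal(unname(act["f", ]),
                 unname(activityScore(expr, paste0("g", 1:6))))
})

test_that("identical groups yield zero fold changes and a flag", {
    set.seed(5)
    expr <- matrix(rexp(300), 30, 10,
                   dimnames = list(paste0("g", 1:30), NULL))
    reg <- data.frame(factor = rep(paste0("g", 1:4), each = 3),
                      target = paste0("g", 5:16), motif_class = "other")
    act <- scoreRegulons(expr, reg)
    out <- activityExpressionCorrelation(expr, act, 1:5, 1:5)
    expect_true(all(out$table$log2FCexpr == 0))
    expect_true(all(out$table$log2FCactivity == 0))
    expect_true(is.na(out$r))
    expect_match(out$flag, "zero variance")
})

test_that("the correlation equals the closed-form Pearson formula", {
    set.seed(6)
    expr <- matrix(rexp(60 * 10, 1 / 5), 60, 10,
                   dimnames = list(paste0("g", 1:60), NULL))
    reg <- data.frame(factor = rep(paste0("g", 1:6), each = 5),
                      target = paste0("g", 11:40), motif_class = "other")
    act <- scoreRegulons(expr, reg)
    out <- activityExpressionCorrelation(expr, act, 1:5, 6:10)
    x <- out$table$log2FCexpr; y <- out$table$log2FCactivity
    manual <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(out$r, manual, tolerance = 1e-12)
})

test_that("rank-auc activity tracks factor expression between groups", {
    ## targets are scaled copies of their factor, so target recovery and
    ## factor expression shift together between the two groups
    set.seed(7)
    nFac <- 10; perFac <- 15; nCells <- 120
    shift <- seq(-1.2, 1.2, length.out = nFac)  # per-factor group effect
    groups <- rep(c("A", "B"), each = nCells / 2)
    facExpr <- t(vapply(seq_len(nFac), function(i)
        exp(rnorm(nCells, mean = 0.8 + ifelse(groups == "A", shift[i], 0),
                  sd = 0.1)), numeric(nCells)))
    rownames(facExpr) <- paste0("F", seq_len(nFac))
    tgt <- do.call(rbind, lapply(seq_len(nFac), function(i)
        outer(runif(perFac, 0.5, 2), facExpr[i, ])))
    rownames(tgt) <- paste0("T", seq_len(nFac * perFac))
    noise <- matrix(rexp(400 * nCells), 400, nCells,
                    dimnames = list(paste0("N", 1:400), NULL))
    expr <- rbind(facExpr, tgt, noise)
    reg <- data.frame(
        factor = rep(rownames(facExpr), each = perFac),
        target = rownames(tgt), motif_class = "other")
    act <- scoreRegulons(expr, reg, topFraction = 0.1)
    out <- activityExpressionCorrelation(expr, act,
                                         which(groups == "A"),
                                         which(groups == "B"))
    expect_gte(out$r, 0.8)
    expect_gt(out$slope, 0)
})

test_that("motif class fractions are exact and order invariant", {
    reg <- data.frame(factor = "Batf_like", target = paste0("g", 1:20),
                      motif_class = rep(c("AP-1", "AICE"), c(7, 13)))
    frac <- motifClassFractions(reg, "Batf_like")
    expect_equal(unname(frac), c(0.35, 0.65, 0))
    expect_equal(sum(frac), 1)

    shuffled <- reg[sample(nrow(reg)), ]
    expect_equal(motifClassFractions(shuffled, "Batf_like"), frac)

    half <- data.frame(factor = "f", target = paste0("g", 1:4),
                       motif_class = c("AP-1", "AP-1", "AICE", "AICE"))
    expect_equal(unname(motifClassFractions(half, "f")), c(0.5, 0.5, 0))
    allAice <- data.frame(factor = "f", target = "g1",
                          motif_class = "AICE")
    expect_equal(unname(motifClassFractions(allAice, "f")), c(0, 1, 0))

    none <- data.frame(factor = "f", target = "g1",
                       motif_class = NA_character_)
    expect_error(motifClassFractions(none, "f"), "no motif annotations")
    bad <- data.frame(factor = "f", target = "g1", motif_class = "ZZZ")
    expect_error(motifClassFractions(bad, "f"), "unknown motif")
})

test_that("simulated regulons couple to the generator's modules", {
    sim <- smallSim()
    reg <- simulateRegulons(sim, seed = 1)
    expect_true(all(c("factor", "target", "motif_class") %in% colnames(reg)))
    expect_true(all(table(reg$factor) > 0))
    batf <- motifClassFractions(reg, "Batf_like")
    nBatf <- sum(reg$factor == "Batf_like")
    expect_equal(unname(batf["AICE"]), round(0.65 * nBatf) / nBatf)
    mods <- geneModules(sim)
    ascTargets <- reg$target[reg$factor == "Prdm1_like"]
    expect_true(all(mods[ascTargets] == "asc"))
})
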