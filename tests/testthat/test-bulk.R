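test_that("RPM normalization scales every sample to one million", {
    one <- matrix(5, 1, 1, dimnames = list("g", "s"))
    expect_equal(rpmNormalize(one)[1, 1], 1e6)

    fixed <- matrix(c(2e5, 8e5, 5e5, 5e5), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_equal(rpmNormalize(fixed), fixed)

    set.seed(1)
    m <- matrix(rpois(80, 20) + 1, 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    rpm <- rpmNormalize(m)
    expect_true(all(abs(colSums(rpm) / 1e6 - 1) < 1e-6))

    bad <- m; bad[, 2] <- 0
    expect_error(rpmNormalize(bad), "s2")
})

test_that("spike rows share the sample's scale factor but not its denominator", {
    m <- rbind(geneA = c(10, 20), `ERCC-1` = c(5, 5))
    colnames(m) <- c("s1", "s2")
    rpm <- rpmNormalize(m)
    expect_equal(rpm["geneA", ], c(s1 = 1e6, s2 = 1e6))
    expect_equal(rpm["ERCC-1", "s1"], 5e5)
    withSpike <- rpmNormalize(m, includeSpikes = TRUE)
    expect_equal(colSums(withSpike), c(s1 = 1e6, s2 = 1e6))
})

test_that("the detection filter requires one fully passing group", {
    m <- rbind(g1 = c(4, 5, 0, 0), g2 = c(4, 1, 2, 9))
    colnames(m) <- paste0("s", 1:4)
    groups <- c("a", "a", "b", "b")
    expect_identical(filterDetected(m, groups), "g1")
    expect_error(filterDetected(m, factor(groups, levels = c("a", "b", "c"))),
                 "empty group")
})

test_that("the detection filter matches a brute-force scan", {
    set.seed(42)
    groups <- rep(c("a", "b"), each = 3)
    for (rep in 1:10) {
        m <- matrix(rexp(180, rate = 1 / 3), 30, 6,
                    dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
        brute <- rownames(m)[vapply(seq_len(30), function(i) {
            any(vapply(unique(groups), function(g)
                all(m[i, groups == g] >= 3), logical(1)))
        }, logical(1))]
        expect_identical(filterDetected(m, groups), brute)
    }
})

test_that("raising the detection threshold never adds genes", {
    set.seed(7)
    m <- matrix(rexp(300, 1 / 4), 50, 6)
    rownames(m) <- paste0("g", 1:50)
    groups <- rep(c("a", "b"), each = 3)
    prev <- filterDetected(m, groups, minRpm = 1)
    for (thr in c(2, 3, 5, 8)) {
        cur <- filterDetected(m, groups, minRpm = thr)
        expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("the molecules-per-cell equation matches the worked substitution", {
    m <- rbind(geneA = 10, `ERCC-1` = 50)
    colnames(m) <- "s1"
    out <- moleculesPerCell(m, spikes = c(`ERCC-1` = 100),
                            cellsPerSample = 1)
    expect_identical(out["geneA", "s1"], 20)
})

test_that("molecules per cell is scale invariant and linear", {
    set.seed(3)
    m <- rbind(matrix(rexp(40, 1 / 50), 10, 4),
               matrix(rexp(20, 1 / 30), 5, 4))
    rownames(m) <- c(paste0("g", 1:10), paste0("ERCC-", 1:5))
    colnames(m) <- paste0("s", 1:4)
    spikes <- setNames(runif(5, 10, 100), paste0("ERCC-", 1:5))
    base <- moleculesPerCell(m, spikes, cellsPerSample = 1000)

    scaled <- m; scaled[, 2] <- scaled[, 2] * 7.3
    expect_equal(moleculesPerCell(scaled, spikes, 1000), base,
                 tolerance = 1e-12)

    doubled <- m; doubled["g3", ] <- doubled["g3", ] * 2
    out <- moleculesPerCell(doubled, spikes, 1000)
    expect_equal(out["g3", ], 2 * base["g3", ], tolerance = 1e-12)
    expect_equal(out[-3, ], base[-3, ], tolerance = 1e-12)

    zero <- m; zero[11:15, 3] <- 0
    expect_error(moleculesPerCell(zero, spikes, 1000), "s3")
})

test_that("noise-free synthetic bulk recovers the generating programs", {
    cfg <- simConfig(nCells = 10, nGenes = 300, bulkNoiseSd = 0, seed = 2)
    panel <- simulateBulkReference(cfg)
    mol <- moleculesPerCell(panel,
                            spikes = S4Vectors::metadata(panel)$spikeReference,
                            cellsPerSample = 1000)
    m <- assay(mol, "molecules")
    tp <- S4Vectors::metadata(panel)$trueProfiles
    for (j in seq_len(ncol(m))) {
        ratio <- m[, j] / tp[rownames(m), colData(panel)$label[j]]
        expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-9)
    }
})

test_that("total mRNA content sums biological molecules per sample", {
    expect_equal(unname(totalMrnaContent(rbind(a = c(3, 1), b = c(4, 1)))),
                 c(7, 2))
    empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("s1", "s2")))
    expect_equal(unname(totalMrnaContent(empty)), c(0, 0))
})

test_that("noise-free totals grow by the configured factor per division", {
    cfg <- simConfig(nCells = 10, nGenes = 300, bulkNoiseSd = 0,
                     mrnaScalePerDivision = 1.3, seed = 2)
    panel <- simulateBulkReference(cfg)
    mol <- moleculesPerCell(panel,
                            spikes = S4Vectors::metadata(panel)$spikeReference,
                            cellsPerSample = 1000)
    tot <- totalMrnaContent(mol)
    lab <- colData(mol)$label
    byDiv <- vapply(c("div0", "div1", "div3", "div5"), function(l)
        mean(tot[lab == l]), numeric(1))
    gaps <- diff(c(0, 1, 3, 5))
    stepRatio <- (byDiv[-1] / byDiv[-4])^(1 / gaps)
    expect_true(all(stepRatio >= 1.2))
})

test_that("BH adjustment matches the hand step-up oracle", {
    p <- c(0.01, 0.02, 0.03, 0.04)
    out <- flagDEG(data.frame(log2FC = rep(2, 4), p = p))
    expect_equal(out$fdr, rep(0.04, 4))

    set.seed(5)
    for (rep in 1:10) {
        pv <- runif(sample(3:20, 1))
        got <- flagDEG(data.frame(log2FC = rep(2, length(pv)), p = pv))$fdr
        expect_equal(got, bhOracle(pv), tolerance = 1e-12)
    }
})

test_that("BH adjustment is order preserving and permutation invariant", {
    set.seed(6)
    pv <- runif(15)
    adj <- flagDEG(data.frame(log2FC = rep(2, 15), p = pv))$fdr
    expect_true(all(diff(adj[order(pv)]) >= -1e-15))
    perm <- sample(15)
    adjPerm <- flagDEG(data.frame(log2FC = rep(2, 15), p = pv[perm]))$fdr
    expect_equal(adjPerm, adj[perm], tolerance = 1e-15)
})

test_that("DEG flags require both the fold-change and FDR gates", {
    out <- flagDEG(data.frame(log2FC = c(0.5, 2, -2),
                              p = c(0.001, 0.001, 0.5)))
    expect_identical(out$significant, c(FALSE, TRUE, FALSE))
    empty <- flagDEG(data.frame(log2FC = numeric(0), p = numeric(0)))
    expect_identical(nrow(empty), 0L)
    expect_error(flagDEG(data.frame(log2FC = 1, p = 1.2)), "\\[0, 1\\]")
})

test_that("the default bulk test separates clearly shifted genes", {
    set.seed(8)
    a <- rbind(up = rexp(4, 1 / 200), flat = rexp(4, 1 / 50))
    b <- rbind(up = rexp(4, 1 / 10), flat = rexp(4, 1 / 50))
    de <- flagDEG(bulkDE(a, b))
    expect_gt(de$log2FC[de$gene == "up"], 1)
    expect_lt(de$p[de$gene == "up"], de$p[de$gene == "flat"])
})
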