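.checkRegulons <- function(regulons) {
    need <- c("factor", "target", "motif_class")
    if (!is.data.frame(regulons) || !all(need %in% colnames(regulons)))
        stop("regulons must be a data.frame with columns ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(regulons$motif_class),
                   c("AP-1", "AICE", "other", NA))
    if (length(bad))
        stop("unknown motif classes: ", paste(bad, collapse = ", "))
    invisible(regulons)
}

#' Score regulon activity per cell
#'
#' Computes a per-cell activity score for each transcription factor's
#' target-gene set (regulon). The default `"rank-auc"` score ranks a
#' cell's genes by expression (descending, ties broken by gene order) and
#' measures the area under the recovery curve of regulon targets within
#' the top `topFraction` of the ranking, normalized so perfect recovery
#' (all targets leading the ranking) scores 1. Because only ranks enter,
#' the score is invariant to any per-cell monotone transform of
#' expression. The `"mean-cubed"` mode instead delegates to
#' [activityScore()] (cube of the mean target expression).
#'
#' @param expr genes x cells expression matrix (imputed or normalized), or
#'   a `SingleCellExperiment` with an `imputed` assay.
#' @param regulons data.frame with columns `factor`, `target`,
#'   `motif_class` (see [readRegulons()] / [simulateRegulons()]). Factors
#'   with no target present in the matrix are dropped with a warning.
#' @param mode `"rank-auc"` (default) or `"mean-cubed"`.
#' @param topFraction fraction of the ranking forming the recovery window.
#' @return factors x cells numeric matrix of activities, with the scoring
#'   mode in `attr(, "mode")`.
#' @export
scoreRegulons <- function(expr, regulons, mode = c("rank-auc", "mean-cubed"),
                          topFraction = 0.05) {
    mode <- match.arg(mode)
    .checkRegulons(regulons)
    m <- .assayOrMatrix(expr, "imputed")
    factors <- unique(regulons$factor)
    targetList <- lapply(factors, function(f) {
        intersect(regulons$target[regulons$factor == f], rownames(m))
    })
    names(targetList) <- factors
    empty <- lengths(targetList) == 0L
    if (any(empty)) {
        warning("dropping factor(s) with no expressed target: ",
                paste(factors[empty], collapse = ", "))
        targetList <- targetList[!empty]
    }
    if (length(targetList) == 0L)
        stop("no regulon has targets in the expression matrix")
    nGenes <- nrow(m)
    nTop <- max(1L, round(topFraction * nGenes))
    if (mode == "mean-cubed") {
        act <- t(vapply(targetList, function(tg)
            colMeans(m[tg, , drop = FALSE])^3, numeric(ncol(m))))
        attr(act, "mode") <- "mean-cubed"
        return(act)
    }
    targetIdx <- lapply(targetList, function(tg) match(tg, rownames(m)))
    act <- matrix(0, nrow = length(targetList), ncol = ncol(m),
                  dimnames = list(names(targetList), colnames(m)))
    for (j in seq_len(ncol(m))) {
        pos <- integer(nGenes)
        pos[order(-m[, j], seq_len(nGenes))] <- seq_len(nGenes)
        for (f in seq_along(targetIdx)) {
            tp <- pos[targetIdx[[f]]]
            tp <- tp[tp <= nTop]
            nT <- length(targetIdx[[f]])
            aucMax <- sum(pmin(seq_len(nTop), nT))
            act[f, j] <- sum(nTop - tp + 1) / aucMax
        }
    }
    attr(act, "mode") <- "rank-auc"
    act
}

#' Correlate activity change with factor expression change
#'
#' For each transcription factor scored in `activity`, computes the log2
#' fold change (with pseudocount `eps`) of the factor's own expression and
#' of its regulon activity between two cell groups, and the Pearson
#' correlation of the two fold-change vectors across factors with its
#' least-squares line — the check that predicted activity tracks factor
#' expression between the post-bifurcation clusters.
#'
#' @param expr genes x cells expression matrix containing the factor genes.
#' @param activity factors x cells matrix from [scoreRegulons()]; factor
#'   names must be gene ids of `expr`.
#' @param cellsA,cellsB column indices or names of the two groups.
#' @param eps pseudocount added to group means before the ratio.
#' @return List with `table` (per-factor `log2FCexpr`, `log2FCactivity`),
#'   `r` (Pearson correlation; NA with `flag` set when fewer than 3
#'   factors or zero variance), `slope`, `intercept` and `flag`.
#' @export
activityExpressionCorrelation <- function(expr, activity, cellsA, cellsB,
                                          eps = 0.01) {
    m <- .assayOrMatrix(expr, "imputed")
    factors <- intersect(rownames(activity), rownames(m))
    if (length(factors) == 0L)
        stop("no factor of the activity matrix is a gene of expr")
    if (length(cellsA) == 0L || length(cellsB) == 0L)
        stop("both cell groups must be non-empty")
    lfc <- function(mat, rows) {
        a <- rowMeans(mat[rows, cellsA, drop = FALSE])
        b <- rowMeans(mat[rows, cellsB, drop = FALSE])
        log2((a + eps) / (b + eps))
    }
    tab <- data.frame(factor = factors,
                      log2FCexpr = lfc(m, factors),
                      log2FCactivity = lfc(activity, factors),
                      stringsAsFactors = FALSE)
    flag <- NULL
    r <- slope <- intercept <- NA_real_
    if (nrow(tab) < 3L) {
        flag <- "fewer than 3 factors; correlation undefined"
    } else if (stats::sd(tab$log2FCexpr) == 0 ||
               stats::sd(tab$log2FCactivity) == 0) {
        flag <- "zero variance in fold changes; correlation undefined"
    } else {
        r <- stats::cor(tab$log2FCexpr, tab$log2FCactivity,
                        method = "pearson")
        fit <- stats::lm(log2FCactivity ~ log2FCexpr, data = tab)
        slope <- unname(stats::coef(fit)[2])
        intercept <- unname(stats::coef(fit)[1])
    }
    list(table = tab, r = r, slope = slope, intercept = intercept,
         flag = flag)
}

#' Motif-class composition of a regulon
#'
#' Fractions of a factor's motif annotations falling in each class of the
#' closed vocabulary (`AP-1`, `AICE`, `other`). Fractions always sum to 1
#' and do not depend on annotation order.
#'
#' @param regulons regulon data.frame (`factor`, `target`, `motif_class`).
#' @param factor factor id with at least one non-missing motif annotation.
#' @return Named numeric vector with entries `AP-1`, `AICE`, `other`.
#' @examples
#' reg <- data.frame(factor = "Batf_like",
#'                   target = paste0("g", 1:20),
#'                   motif_class = rep(c("AP-1", "AICE"), c(7, 13)))
#' motifClassFractions(reg, "Batf_like")
#' @export
motifClassFractions <- function(regulons, factor) {
    .checkRegulons(regulons)
    ann <- regulons$motif_class[regulons$factor == factor]
    ann <- ann[!is.na(ann)]
    if (length(ann) == 0L)
        stop("factor '", factor, "' has no motif annotations")
    counts <- table(base::factor(ann, levels = c("AP-1", "AICE", "other")))
    stats::setNames(as.numeric(counts) / length(ann),
                    c("AP-1", "AICE", "other"))
}

#' Simulate regulons coupled to the generator's modules
#'
#' Builds a synthetic regulon table whose factors are marker genes of the
#' simulation and whose targets are drawn from the factor's own module, so
#' regulon activity co-varies with factor expression by construction
#' (emulating inferred transcription-factor target sets without running
#' network inference). The AP-1 family factor (`Batf_like`) receives a
#' 35%/65% AP-1/AICE motif split; other factors are annotated `other`.
#'
#' @param sim a simulation from [simulateExperiment()].
#' @param targetsPerFactor targets sampled per factor (capped at the
#'   module size).
#' @param nNeutral number of additional factors drawn from non-module
#'   genes with random targets (expected fold change ~ 0 between
#'   branches).
#' @param seed seed for target sampling.
#' @return Regulon data.frame (`factor`, `target`, `motif_class`).
#' @export
simulateRegulons <- function(sim, targetsPerFactor = 20, nNeutral = 4,
                             seed = 1) {
    modules <- geneModules(sim)
    hubs <- c(Prdm1_like = "asc", Irf4_like = "asc", Xbp1_like = "asc",
              Myc_like = "oxphos", Ldha_like = "oxphos",
              Klf6_like = "inflam", Ifngr1_like = "inflam",
              Pax5_like = "bcell", Spib_like = "bcell",
              Atf6_like = "erstress", Batf_like = "activation",
              Zbtb32_like = "activation")
    hubs <- hubs[names(hubs) %in% names(modules)]
    set.seed(seed)
    rows <- list()
    for (f in names(hubs)) {
        pool <- setdiff(names(modules)[modules == hubs[[f]]], f)
        tg <- sample(pool, min(targetsPerFactor, length(pool)))
        motif <- if (f == "Batf_like") {
            nAice <- round(0.65 * length(tg))
            c(rep("AICE", nAice), rep("AP-1", length(tg) - nAice))
        } else rep("other", length(tg))
        rows[[f]] <- data.frame(factor = f, target = tg,
                                motif_class = motif,
                                stringsAsFactors = FALSE)
    }
    neutralPool <- names(modules)[modules == "none"]
    nNeutral <- min(nNeutral, length(neutralPool))
    if (nNeutral > 0L) {
        fs <- sample(neutralPool, nNeutral)
        for (f in fs) {
            tg <- sample(setdiff(neutralPool, f),
                         min(targetsPerFactor, length(neutralPool) - 1L))
            rows[[f]] <- data.frame(factor = f, target = tg,
                                    motif_class = "other",
                                    stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    .checkRegulons(out)
}
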