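#' Read a 10x-style MTX triplet directory
#'
#' Reads `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `features.tsv` and `barcodes.tsv` from a directory into a
#' `SingleCellExperiment` with a sparse `counts` assay. Duplicate gene ids
#' are collapsed by summing their rows, with a warning.
#'
#' @param dir directory holding the three files.
#' @param featureColumn column of `features.tsv` providing gene ids.
#' @return A `SingleCellExperiment` (genes x cells).
#' @export
readMtxTriplet <- function(dir, featureColumn = 1) {
    paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("missing file(s): ", paste(missing, collapse = ", "))
    m <- as(Matrix::readMM(paths[1]), "CsparseMatrix")
    feats <- utils::read.delim(paths[2], header = FALSE,
                               stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(paths[3], header = FALSE,
                                  stringsAsFactors = FALSE)[, 1]
    if (nrow(feats) != nrow(m))
        stop("dimension mismatch: ", nrow(m), " matrix rows vs ",
             nrow(feats), " features")
    if (length(barcodes) != ncol(m))
        stop("dimension mismatch: ", ncol(m), " matrix columns vs ",
             length(barcodes), " barcodes")
    genes <- as.character(feats[, featureColumn])
    if (anyDuplicated(genes)) {
        warning("collapsing ", sum(duplicated(genes)),
                " duplicate gene id(s) by sum")
        dense <- rowsum(as.matrix(m),
                        group = base::factor(genes, levels = unique(genes)))
        m <- as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
        genes <- unique(genes)
    }
    dimnames(m) <- list(genes, barcodes)
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a 10x-style MTX triplet directory
#'
#' @param x `SingleCellExperiment` or genes x cells matrix of counts.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeMtxTriplet <- function(x, dir) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts") else x
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(as(as(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                          "generalMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(m) %||% as.character(seq_len(nrow(m))),
               file.path(dir, "features.tsv"))
    writeLines(colnames(m) %||% as.character(seq_len(ncol(m))),
               file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Malformed lines are reported with their line number.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    for (i in seq_along(lines)) {
        parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3L)
            stop("malformed GMT line ", i,
                 ": expected name, description and >= 1 gene")
        out[[parts[1]]] <- parts[-(1:2)]
    }
    out
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(names(sets), function(n)
        paste(c(n, n, sets[[n]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a TSV expression matrix
#'
#' A header row of sample/cell ids and a first column of gene ids.
#'
#' @param path file path.
#' @return `readTsvMatrix`: a numeric matrix with dimnames.
#' @export
readTsvMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyDuplicated(genes)) {
        warning("collapsing ", sum(duplicated(genes)),
                " duplicate gene id(s) by sum")
        m <- rowsum(m, group = base::factor(genes, levels = unique(genes)))
        genes <- unique(genes)
    }
    rownames(m) <- genes
    m
}

#' @rdname readTsvMatrix
#' @param x matrix to write.
#' @param idColumn name of the gene-id column in the header.
#' @export
writeTsvMatrix <- function(x, path, idColumn = "gene") {
    df <- data.frame(rownames(x) %||% seq_len(nrow(x)), x,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[1] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a spike-in reference TSV
#'
#' Two columns: `spike_id` and `molecules` (known input molecule counts).
#'
#' @param path file path.
#' @return data.frame with `spike_id` and `molecules`.
#' @export
readSpikeReference <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("spike_id", "molecules") %in% colnames(df)))
        stop("spike reference needs columns spike_id and molecules")
    if (any(df$molecules <= 0)) stop("molecule counts must be positive")
    if (anyDuplicated(df$spike_id)) stop("duplicate spike ids")
    df
}

#' Read a regulon definition TSV
#'
#' Three columns: `factor`, `target`, `motif_class` (one of `AP-1`,
#' `AICE`, `other`).
#'
#' @param path file path.
#' @return Validated regulon data.frame.
#' @export
readRegulons <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    .checkRegulons(df)
}

#' Write / read a labeled reference panel
#'
#' The panel matrix goes to `<prefix>_matrix.tsv` (genes + spikes by
#' replicates) and the per-column labels (`label`, `track`, `replicate`)
#' to `<prefix>_samples.tsv`.
#'
#' @param panel `SummarizedExperiment` from [simulateBulkReference()].
#' @param prefix output path prefix.
#' @return `writeReferencePanel`: the prefix, invisibly;
#'   `readReferencePanel`: the reassembled `SummarizedExperiment`.
#' @export
writeReferencePanel <- function(panel, prefix) {
    writeTsvMatrix(as.matrix(SummarizedExperiment::assay(panel, 1)),
                   paste0(prefix, "_matrix.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(panel))
    cd <- cbind(sample = rownames(cd), cd)
    utils::write.table(cd, paste0(prefix, "_samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(prefix)
}

#' @rdname writeReferencePanel
#' @param spikePrefix row-name prefix marking spike rows on re-read.
#' @export
readReferencePanel <- function(prefix, spikePrefix = "ERCC-") {
    m <- readTsvMatrix(paste0(prefix, "_matrix.tsv"))
    cd <- utils::read.delim(paste0(prefix, "_samples.tsv"), header = TRUE,
                            stringsAsFactors = FALSE)
    if (nrow(cd) != ncol(m))
        stop("sample table does not match the matrix columns")
    SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = m),
        rowData = S4Vectors::DataFrame(
            isSpike = startsWith(rownames(m), spikePrefix),
            row.names = rownames(m)),
        colData = S4Vectors::DataFrame(cd[, setdiff(colnames(cd), "sample"),
                                          drop = FALSE],
                                       row.names = cd$sample))
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults. Keys mirror the arguments of [simConfig()] plus the stage
#' parameters of [runPipeline()].
#'
#' @param path YAML or JSON file.
#' @return Named list of configuration values.
#' @export
readPipelineConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    known <- c(names(formals(simConfig)),
               "numDim", "perplexity", "k", "ka", "npcs", "t",
               "minCellsPerGene", "minUmiPerCell", "nTop", "nPerm",
               "topFraction", "outDir", "verbose")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg
}
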