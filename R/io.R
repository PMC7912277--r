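#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (gene_id, symbol, length_bp) and
#' `barcodes.tsv` (optionally gzipped). Genes are rows, cells are columns;
#' values must be integers and are preserved exactly. Line counts of the
#' annotation files must match the matrix dimensions.
#'
#' Duplicate gene symbols are disambiguated by suffixing ".1", ".2", ...
#' in order of occurrence (the Cell Ranger convention); `gene_id` must be
#' unique as read.
#'
#' @param dir Directory containing the three files.
#' @return A [SingleCellExperiment::SingleCellExperiment] with integer
#'   assay `counts`, rowData from features, and barcodes as column names.
#' @importFrom Matrix readMM
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame
#' @export
readMtx <- function(dir) {
    pick <- function(base) {
        for (f in file.path(dir, c(base, paste0(base, ".gz"))))
            if (file.exists(f)) return(f)
        stop("format error: missing ", base, " in ", dir)
    }
    mtxFile <- pick("matrix.mtx")
    m <- as.matrix(Matrix::readMM(mtxFile))
    if (any(m != round(m)))
        stop("format error: non-integer entries in ", mtxFile)
    feat <- utils::read.delim(pick("features.tsv"), header = FALSE,
                              stringsAsFactors = FALSE)
    bc <- readLines(pick("barcodes.tsv"))
    if (nrow(feat) != nrow(m))
        stop("format error: features.tsv has ", nrow(feat),
             " lines but matrix.mtx has ", nrow(m), " rows")
    if (length(bc) != ncol(m))
        stop("format error: barcodes.tsv has ", length(bc),
             " lines but matrix.mtx has ", ncol(m), " columns")
    if (ncol(feat) < 3L)
        stop("format error: features.tsv needs gene_id, symbol, length_bp")
    genes <- data.frame(gene_id = as.character(feat[[1L]]),
                        symbol = make.unique(as.character(feat[[2L]]),
                                             sep = "."),
                        length_bp = as.integer(feat[[3L]]),
                        stringsAsFactors = FALSE)
    if (anyDuplicated(genes$gene_id))
        stop("format error: duplicated gene_id in features.tsv")
    if (any(is.na(genes$length_bp)) || any(genes$length_bp < 1L))
        stop("format error: gene lengths must be integers >= 1")
    storage.mode(m) <- "integer"
    dimnames(m) <- list(genes$gene_id, bc)
    SingleCellExperiment(assays = list(counts = m),
                         rowData = DataFrame(genes,
                                             row.names = genes$gene_id))
}

#' Write a 10x-style Matrix Market triplet directory
#'
#' @param sce A `SingleCellExperiment` with assay `counts` and rowData
#'   columns `gene_id`, `symbol`, `length_bp` (or a plain integer matrix
#'   plus a `genes` table).
#' @param dir Output directory (created if needed).
#' @param genes Gene table when `sce` is a plain matrix.
#' @return Invisibly, the directory path.
#' @importFrom Matrix writeMM
#' @importFrom SummarizedExperiment assay rowData
#' @export
writeMtx <- function(sce, dir, genes = NULL) {
    if (is(sce, "SingleCellExperiment")) {
        m <- assay(sce, "counts")
        genes <- as.data.frame(rowData(sce))[, c("gene_id", "symbol",
                                                 "length_bp")]
    } else m <- sce
    stopifnot(is.matrix(m) || is(m, "Matrix"), !is.null(genes))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    utils::write.table(genes, file.path(dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(colnames(m) %||% sprintf("CELL%05d", seq_len(ncol(m))),
               file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' Read a dense genes-by-cells CSV count matrix
#'
#' First column gene ids, header row barcodes; integer values required.
#'
#' @param path CSV file (optionally gzipped).
#' @return Integer matrix, genes x cells.
#' @export
readDenseCsv <- function(path) {
    df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || any(m != round(m)))
        stop("format error: non-integer entries in ", path)
    storage.mode(m) <- "integer"
    rownames(m) <- as.character(df[[1L]])
    m
}

#' Write a dense genes-by-cells CSV count matrix
#' @param m Integer matrix with gene row names and barcode column names.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeDenseCsv <- function(m, path) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated MSigDB format: set name, description, then member genes.
#' Duplicate genes within a set are removed keeping first occurrence; empty
#' sets and duplicated set names are rejected.
#'
#' @param path GMT file (optionally gzipped).
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(stats::setNames(list(), character(0)))
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("format error: GMT line ", i, " has fewer than 3 fields")
        sets[[f[1L]]] <- unique(f[-(1:2)])
    }
    if (anyDuplicated(vapply(seq_along(lines), function(i)
        strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]][1L], character(1L))))
        stop("format error: duplicated set names in ", path)
    sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional per-set description column (default "na").
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    if (any(!nzchar(names(sets))) || anyDuplicated(names(sets)))
        stop("set names must be unique and non-empty")
    if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
    desc <- descriptions %||% rep("na", length(sets))
    writeLines(vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
        character(1L)), path)
    invisible(path)
}

#' Read a regulon network TSV
#'
#' Four tab-separated columns with header: `tf`, `target`, `mode`,
#' `likelihood`. Rows are grouped by TF into [Regulon-class] objects;
#' modes outside `[-1, 1]`, likelihoods outside `(0, 1]`, duplicate
#' (tf, target) pairs and self-edges are rejected with the offending row
#' number.
#'
#' @param path TSV file (optionally gzipped).
#' @return A [RegulonList-class].
#' @export
readRegulons <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("tf", "target", "mode", "likelihood")
    if (!all(need %in% names(df)))
        stop("format error: regulon TSV needs columns ",
             paste(need, collapse = ", "))
    bad <- which(!is.finite(df$mode) | df$mode < -1 | df$mode > 1)
    if (length(bad))
        stop("validation error: mode outside [-1, 1] at row ", bad[1L])
    bad <- which(!is.finite(df$likelihood) | df$likelihood <= 0 |
                     df$likelihood > 1)
    if (length(bad))
        stop("validation error: likelihood outside (0, 1] at row ", bad[1L])
    bad <- which(duplicated(df[, c("tf", "target")]))
    if (length(bad))
        stop("validation error: duplicated (tf, target) pair at row ",
             bad[1L])
    bad <- which(df$tf == df$target)
    if (length(bad))
        stop("validation error: self-edge at row ", bad[1L])
    regs <- lapply(split(df, factor(df$tf, levels = unique(df$tf))),
                   function(d) Regulon(d$tf[1L], d$target, d$mode,
                                       d$likelihood))
    RegulonList(unname(regs))
}

#' Write a regulon network TSV
#' @param regulons A [RegulonList-class] (or list of [Regulon-class]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeRegulons <- function(regulons, path) {
    df <- do.call(rbind, lapply(as.list(regulons), function(r)
        cbind(tf = regulonTF(r), regulonTargets(r))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write ground truth as JSON
#'
#' Serializes the simulator's [GroundTruth-class] (gene table, baseline
#' log means, regulon edges, activity matrix, labels, phase programs) to a
#' JSON file so a simulated dataset can be audited without re-running the
#' generator.
#'
#' @param truth A [GroundTruth-class].
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
writeTruthJson <- function(truth, path) {
    edges <- do.call(rbind, lapply(as.list(truth@regulons), function(r)
        cbind(tf = regulonTF(r), regulonTargets(r))))
    obj <- list(genes = truth@genes,
                base_log_mean = as.list(truth@baseLogMean),
                regulons = edges,
                activity_matrix = truth@activityMatrix,
                populations = truth@populations,
                cycle_fraction = truth@cycleFraction,
                cell_labels = truth@cellLabels,
                cycle_labels = truth@cycleLabels,
                s_genes = truth@sGenes, g2m_genes = truth@g2mGenes,
                hv_genes = truth@hvGenes,
                hv_population = truth@hvPopulation)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
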