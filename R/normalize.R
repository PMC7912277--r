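#' TPM normalization
#'
#' Transcripts per kilobase million: each gene's count is divided by the
#' gene length in kilobases, and these rates are rescaled cell by cell so
#' every cell sums to 1e6.
#'
#' @param counts Integer genes x cells matrix, or a
#'   `SingleCellExperiment` with assay `counts` and rowData `length_bp`.
#' @param lengths Gene lengths in bp (ignored for a
#'   `SingleCellExperiment`).
#' @return Numeric matrix of TPM values (columns sum to 1e6), or the
#'   `SingleCellExperiment` with an added `tpm` assay.
#' @examples
#' m <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "c1"))
#' tpmNormalize(m, lengths = c(1000, 2000))
#' @export
setGeneric("tpmNormalize",
           function(counts, lengths = NULL) standardGeneric("tpmNormalize"))

.tpm <- function(counts, lengths) {
    stopifnot(length(lengths) == nrow(counts))
    if (any(!is.finite(lengths)) || any(lengths < 1))
        stop("gene lengths must be >= 1 bp")
    zero <- colSums(counts) == 0
    if (any(zero))
        stop("all-zero cell(s): ",
             paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
    rate <- counts / (lengths / 1000)
    sweep(rate, 2L, colSums(rate), "/") * 1e6
}

#' @rdname tpmNormalize
setMethod("tpmNormalize", "matrix",
          function(counts, lengths = NULL) .tpm(counts, lengths))

#' @rdname tpmNormalize
#' @importFrom SummarizedExperiment assay assay<- rowData
setMethod("tpmNormalize", "SingleCellExperiment",
          function(counts, lengths = NULL) {
    assay(counts, "tpm") <- .tpm(assay(counts, "counts"),
                                 rowData(counts)$length_bp)
    counts
})

#' Log10 with pseudovalue
#'
#' `log10(TPM + pseudo)` with the conventional pseudovalue 1e-4, so that a
#' TPM of zero maps to -4 and values of 1e6 map to ~6.
#'
#' @param x TPM matrix (or vector), or a `SingleCellExperiment` with a
#'   `tpm` assay.
#' @param pseudo Pseudovalue added before the logarithm.
#' @return Same shape as `x` on the log10 scale (`logtpm` assay for a
#'   `SingleCellExperiment`).
#' @export
setGeneric("log10Tpm", function(x, pseudo = 1e-4) standardGeneric("log10Tpm"))

#' @rdname log10Tpm
setMethod("log10Tpm", "ANY", function(x, pseudo = 1e-4) log10(x + pseudo))

#' @rdname log10Tpm
setMethod("log10Tpm", "SingleCellExperiment", function(x, pseudo = 1e-4) {
    assay(x, "logtpm") <- log10(assay(x, "tpm") + pseudo)
    x
})

#' Seurat-style log normalization
#'
#' `ln(1 + count / colsum * scale)` with a scale factor of 10,000 — the
#' LogNormalize operating scale used for clustering and differential
#' expression.
#'
#' @param counts Integer genes x cells matrix, or a `SingleCellExperiment`
#'   with assay `counts`.
#' @param scale Scale factor.
#' @return Matrix of log-normalized values (natural log), or the
#'   `SingleCellExperiment` with an added `lognorm` assay.
#' @export
setGeneric("logNormalizeCounts",
           function(counts, scale = 1e4) standardGeneric("logNormalizeCounts"))

.lognorm <- function(counts, scale) {
    cs <- colSums(counts)
    if (any(cs == 0))
        stop("all-zero cell(s): ",
             paste(colnames(counts)[cs == 0] %||% which(cs == 0),
                   collapse = ", "))
    log1p(sweep(counts, 2L, cs, "/") * scale)
}

#' @rdname logNormalizeCounts
setMethod("logNormalizeCounts", "matrix",
          function(counts, scale = 1e4) .lognorm(counts, scale))

#' @rdname logNormalizeCounts
setMethod("logNormalizeCounts", "SingleCellExperiment",
          function(counts, scale = 1e4) {
    assay(counts, "lognorm") <- .lognorm(assay(counts, "counts"), scale)
    counts
})

#' Filter genes by detection
#'
#' Keeps genes with a nonzero count in at least `minCells` cells ("measured
#' in" is read as count > 0); gene order is preserved and the filter is
#' idempotent.
#'
#' @param counts Integer genes x cells matrix or `SingleCellExperiment`.
#' @param minCells Minimum number of cells with a nonzero count; a gene
#'   detected in exactly `minCells` cells is retained.
#' @return The input with failing genes dropped.
#' @export
setGeneric("filterGenes",
           function(counts, minCells = 3L) standardGeneric("filterGenes"))

#' @rdname filterGenes
setMethod("filterGenes", "matrix", function(counts, minCells = 3L) {
    counts[rowSums(counts > 0) >= minCells, , drop = FALSE]
})

#' @rdname filterGenes
setMethod("filterGenes", "SingleCellExperiment",
          function(counts, minCells = 3L) {
    counts[rowSums(assay(counts, "counts") > 0) >= minCells, ]
})
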