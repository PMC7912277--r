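#' Pseudobulk aggregation
#'
#' Sums TPM values across cells and rescales the sum back to 1e6, giving a
#' bulk-like TPM profile of the cell population. Invariant under
#' duplicating cells and equal to the single cell's profile when there is
#' only one.
#'
#' @param x Genes x cells TPM matrix (at least one cell).
#' @return Named numeric vector summing to 1e6.
#' @export
pseudobulk <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    if (ncol(x) < 1L) stop("pseudobulk needs at least one cell")
    s <- rowSums(x)
    s / sum(s) * 1e6
}

#' Match pseudobulk profiles against a bulk panel
#'
#' Spearman correlation of each pseudobulk profile with every column of a
#' bulk TPM panel, computed on `log10(TPM + pseudo)` over the shared-gene
#' intersection. Because Spearman works on ranks, the result is invariant
#' to any monotone transform of either profile. Rows are sorted by
#' decreasing correlation (ties broken by sample label) and the best match
#' is flagged.
#'
#' @param pb Named numeric pseudobulk vector, or genes x profiles matrix.
#' @param panel Genes x samples bulk TPM matrix with gene row names.
#' @param pseudo Pseudovalue before the log.
#' @param minShared Minimum size of the shared-gene intersection.
#' @return `data.frame` with columns `pseudobulk`, `sample`, `rho`,
#'   `best`.
#' @export
matchBulk <- function(pb, panel, pseudo = 1e-4, minShared = 100L) {
    if (is.null(dim(pb))) pb <- matrix(pb, ncol = 1L,
                                       dimnames = list(names(pb), "sc"))
    shared <- intersect(rownames(pb), rownames(panel))
    if (length(shared) < minShared)
        stop("only ", length(shared), " shared genes (need >= ", minShared,
             ")")
    lp <- log10(pb[shared, , drop = FALSE] + pseudo)
    lb <- log10(panel[shared, , drop = FALSE] + pseudo)
    rho <- stats::cor(lp, lb, method = "spearman")
    out <- do.call(rbind, lapply(seq_len(nrow(rho)), function(i) {
        d <- data.frame(pseudobulk = rownames(rho)[i],
                        sample = colnames(rho), rho = rho[i, ],
                        stringsAsFactors = FALSE)
        d <- d[order(-d$rho, d$sample), ]
        d$best <- seq_len(nrow(d)) == 1L
        d
    }))
    rownames(out) <- NULL
    out
}
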