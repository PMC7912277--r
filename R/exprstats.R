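#' Per-gene summary statistics with loess-de-trended variance
#'
#' Computes, for every gene, the mean and variance of log10 TPM across
#' cells, the fraction of cells in which the gene is detected (count > 0),
#' and the residual variance after subtracting a loess fit of variance on
#' mean. De-trending removes the mean-variance relationship so that
#' residual variance ranks genuinely heterogeneous genes rather than merely
#' highly expressed ones.
#'
#' @param logtpm Genes x cells matrix of log10 TPM values.
#' @param counts Matching count matrix (for detection fractions).
#' @param span,degree Loess parameters for the variance trend (span 0.3,
#'   quadratic local fit).
#' @return `data.frame` with columns `gene`, `mean`, `variance`,
#'   `residual_variance`, `detection_fraction`.
#' @examples
#' cfg <- simConfig(nGenes = 300, nTFs = 3, targetsPerTF = 20,
#'                  populations = data.frame(label = "A", n_cells = 50))
#' sce <- simulateCounts(makeTruth(cfg), cfg)
#' sce <- log10Tpm(tpmNormalize(sce))
#' head(geneStats(SummarizedExperiment::assay(sce, "logtpm"),
#'                SummarizedExperiment::assay(sce, "counts")))
#' @export
geneStats <- function(logtpm, counts, span = 0.3, degree = 2) {
    stopifnot(identical(dim(logtpm), dim(counts)))
    if (nrow(logtpm) < 10L)
        stop("loess error: need at least 10 genes, got ", nrow(logtpm))
    mu <- rowMeans(logtpm)
    v <- rowSums((logtpm - mu)^2) / (ncol(logtpm) - 1L)
    fit <- stats::loess(v ~ mu, span = span, degree = degree)
    data.frame(gene = rownames(logtpm) %||% seq_len(nrow(logtpm)),
               mean = mu, variance = v,
               residual_variance = v - stats::predict(fit, mu),
               detection_fraction = rowMeans(counts > 0),
               row.names = NULL, stringsAsFactors = FALSE)
}

# Vectorized two-sided Wilcoxon rank-sum p-values for every row of
# cbind(a, b). Uses the exact null distribution when a gene has no ties and
# both groups have <= 50 cells, otherwise the tie-corrected normal
# approximation with continuity correction (the stats::wilcox.test policy).
.rankSumP <- function(a, b) {
    nA <- ncol(a); nB <- ncol(b); n <- nA + nB
    x <- cbind(a, b)
    p <- numeric(nrow(x))
    allTied <- logical(nrow(x))
    for (g in seq_len(nrow(x))) {
        r <- rank(x[g, ])
        U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
        tab <- table(x[g, ])
        hasTies <- any(tab > 1L)
        if (length(tab) == 1L) { p[g] <- 1; allTied[g] <- TRUE; next }
        if (!hasTies && max(nA, nB) <= 50L) {
            p[g] <- if (U > nA * nB / 2)
                2 * stats::pwilcox(U - 1, nA, nB, lower.tail = FALSE)
            else 2 * stats::pwilcox(U, nA, nB)
            p[g] <- min(1, p[g])
        } else {
            tieSum <- sum(tab^3 - tab)
            sigma <- sqrt(nA * nB / 12 * ((n + 1) - tieSum / (n * (n - 1))))
            z <- U - nA * nB / 2
            z <- (z - sign(z) * 0.5) / sigma   # continuity correction
            p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
        }
    }
    list(p = p, allTied = allTied)
}

#' Two-group Wilcoxon differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two groups of cells on
#' log-normalized expression, with the Seurat-style average log fold change
#' `ln(mean(expm1(a)) + 1) - ln(mean(expm1(b)) + 1)`, detection fractions
#' per group, and Benjamini-Hochberg adjusted p-values over all tested
#' genes. Genes tied across both groups get p = 1 (kept, with a warning).
#'
#' @param x Genes x cells matrix of log-normalized values (natural log).
#' @param cellsA,cellsB Column names or indices of the two groups (each at
#'   least 3 cells).
#' @return `data.frame` with columns `gene`, `p_value`, `avg_logFC`,
#'   `pct_1`, `pct_2`, `adj_p`.
#' @seealso [groupSignature()] to convert the table into a signed-z
#'   signature.
#' @export
wilcoxonDE <- function(x, cellsA, cellsB) {
    a <- x[, cellsA, drop = FALSE]
    b <- x[, cellsB, drop = FALSE]
    if (ncol(a) < 3L || ncol(b) < 3L)
        stop("both groups need at least 3 cells")
    rs <- .rankSumP(a, b)
    if (any(rs$allTied))
        warning(sum(rs$allTied),
                " gene(s) tied across both groups; p set to 1")
    data.frame(gene = rownames(x) %||% seq_len(nrow(x)),
               p_value = rs$p,
               avg_logFC = log(rowMeans(expm1(a)) + 1) -
                   log(rowMeans(expm1(b)) + 1),
               pct_1 = rowMeans(a > 0), pct_2 = rowMeans(b > 0),
               adj_p = benjaminiHochberg(rs$p),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate correction: the adjusted value of the i-th
#' order statistic is `min over j >= i of min(1, p_(j) * m / j)`, returned
#' in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must be numeric in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Signed-z differential signature
#'
#' Converts a differential-expression table into a per-gene signature:
#' `sign(avg_logFC) * qnorm(p/2, lower.tail = FALSE)` with p floored at
#' 1e-300. The signed-z scale makes scores comparable across genes and
#' suitable for enrichment analysis; p = 1 maps to 0.
#'
#' @param de A `data.frame` from [wilcoxonDE()] (columns `gene`,
#'   `p_value`, `avg_logFC`).
#' @return Named numeric vector, positive for genes up in group A.
#' @export
groupSignature <- function(de) {
    stopifnot(nrow(de) > 0L,
              all(c("gene", "p_value", "avg_logFC") %in% names(de)))
    z <- stats::qnorm(pmax(de$p_value, 1e-300) / 2, lower.tail = FALSE)
    stats::setNames(sign(de$avg_logFC) * z, de$gene)
}
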