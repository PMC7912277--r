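#' Per-cell signatures
#'
#' Scores each cell against the whole dataset: per gene, the z-score of
#' the cell's log10 TPM value relative to the dataset mean and (population)
#' standard deviation across cells. Genes with zero variance are dropped
#' from all signatures; the sd is floored at 1e-8. The z scale keeps highly
#' expressed genes from dominating downstream enrichment scores.
#'
#' @param x Genes x cells matrix of log10 TPM values, at least 2 cells.
#' @return Genes x cells matrix of signature scores; each row sums to ~0.
#' @export
cellSignatures <- function(x) {
    if (ncol(x) < 2L) stop("per-cell signatures need at least 2 cells")
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans((x - mu)^2))   # population sd (divisor n)
    keep <- sdv > 0
    (x[keep, , drop = FALSE] - mu[keep]) / pmax(sdv[keep], 1e-8)
}

# Sign-matched NES scaling against a pooled null.
.poolNes <- function(es, pool) {
    if (all(pool == 0)) stop("degenerate null: all permuted scores are zero")
    dPos <- mean(abs(pool[pool > 0]))
    dNeg <- mean(abs(pool[pool < 0]))
    dAll <- mean(abs(pool))
    if (!is.finite(dPos)) dPos <- dAll
    if (!is.finite(dNeg)) dNeg <- dAll
    ifelse(es > 0, es / dPos, ifelse(es < 0, es / dNeg, 0))
}

#' Per-cell regulon or pathway activity
#'
#' Computes, for every cell signature and every regulon (or gene set), the
#' enrichment score and a NES against a gene-label permutation null. One
#' seeded null pool per object is shared across all cells (permutations of
#' gene labels applied to every cell's signature, pooled), so activities
#' are on a common scale and directly comparable between cells.
#'
#' @param x Genes x cells matrix of cell signatures (see
#'   [cellSignatures()]), or of log10 TPM values with
#'   `signatures = TRUE`.
#' @param objs A [RegulonList-class] or a named list of gene sets.
#' @param nPerm Permutations per object (shared across cells).
#' @param seed Seed for the permutation stream.
#' @param weight GSEA weight exponent (gene sets only).
#' @param minSize Minimum targets/members in the universe; smaller objects
#'   are skipped with a warning.
#' @param signatures If `TRUE`, convert `x` with [cellSignatures()] first.
#' @return Cells x objects numeric matrix of NES values; column order
#'   follows the input objects.
#' @export
scActivity <- function(x, objs, nPerm = 100L, seed = NULL, weight = 1,
                       minSize = 10L, signatures = FALSE) {
    if (signatures) x <- cellSignatures(x)
    genes <- rownames(x)
    if (is.null(genes)) stop("signature matrix needs gene row names")
    nCells <- ncol(x)
    isReg <- is(objs, "RegulonList") ||
        (is.list(objs) && length(objs) && is(objs[[1L]], "Regulon"))
    objList <- as.list(objs)
    sizes <- vapply(objList, function(o) {
        members <- if (is(o, "Regulon")) regulonTargets(o)$target else o
        sum(members %in% genes)
    }, integer(1L))
    if (any(sizes < minSize)) {
        warning("skipping ", sum(sizes < minSize),
                " object(s) below minSize: ",
                paste(names(objList)[sizes < minSize], collapse = ", "))
        objList <- objList[sizes >= minSize]
    }
    if (!length(objList)) stop("no eligible regulon or gene set")
    act <- matrix(0, nCells, length(objList),
                  dimnames = list(colnames(x), names(objList)))

    if (isReg) {
        # regulon ES is a weighted dot product: vectorize over cells, and
        # permute gene labels by permuting the rows of x
        W <- matrix(0, length(genes), length(objList))
        rownames(W) <- genes
        sl <- numeric(length(objList))
        for (k in seq_along(objList)) {
            tg <- regulonTargets(objList[[k]])
            tg <- tg[tg$target %in% genes, , drop = FALSE]
            W[tg$target, k] <- tg$likelihood * tg$mode
            sl[k] <- sum(tg$likelihood)
        }
        esObs <- crossprod(x, W)
        esObs <- sweep(esObs, 2L, sl, "/")
        pools <- withSeed(seed, {
            ps <- vector("list", nPerm)
            for (i in seq_len(nPerm)) {
                prm <- sample(nrow(x))
                e <- crossprod(x[prm, , drop = FALSE], W)
                ps[[i]] <- sweep(e, 2L, sl, "/")
            }
            ps
        })
        for (k in seq_along(objList)) {
            pool <- unlist(lapply(pools, function(e) e[, k]),
                           use.names = FALSE)
            act[, k] <- .poolNes(esObs[, k], pool)
        }
    } else {
        # gene sets: per cell ranking, shared random hit positions per
        # permutation across cells
        ords <- apply(x, 2L, .gseaOrder)
        N <- nrow(x)
        hitpos <- lapply(objList, function(g) which(genes %in% g))
        permIdx <- withSeed(seed, lapply(seq_len(nPerm), function(i)
            lapply(lengths(hitpos), function(nh) sort(sample.int(N, nh)))))
        for (c in seq_len(nCells)) {
            s <- x[ords[, c], c]
            absw <- abs(s)^weight
            pos <- match(seq_len(N), ords[, c])  # rank of each gene row
            for (k in seq_along(objList))
                act[c, k] <- .gseaStat(absw, sort(pos[hitpos[[k]]]), N)
        }
        for (k in seq_along(objList)) {
            pool <- numeric(0)
            for (c in seq_len(nCells)) {
                s <- x[ords[, c], c]
                absw <- abs(s)^weight
                pool <- c(pool, vapply(seq_len(nPerm), function(i)
                    .gseaStat(absw, permIdx[[i]][[k]], N), numeric(1L)))
            }
            obs <- act[, k]
            act[, k] <- .poolNes(obs, pool)
        }
    }
    act
}

#' Cell-cycle module scores
#'
#' Scores every cell for S-phase and G2/M-phase programs: the mean
#' log-normalized expression of the phase gene list minus the mean of
#' expression-matched control genes. Controls are drawn per list gene
#' (`nCtrl` draws with replacement) from the same dataset-wide
#' average-expression bin, with genes binned into `nBins` quantile bins —
#' so a list scores ~0 unless its genes deviate from expression-matched
#' background.
#'
#' @param x Genes x cells matrix of log-normalized expression.
#' @param sGenes,g2mGenes Phase program gene ids; at least 5 of each must
#'   be present in the matrix.
#' @param nBins Number of average-expression bins.
#' @param nCtrl Control genes sampled per list gene.
#' @param seed Seed for control sampling.
#' @return `data.frame` with columns `cell`, `s_score`, `g2m_score`.
#' @seealso [assignPhase()]
#' @export
cellCycleScores <- function(x, sGenes, g2mGenes, nBins = 24L, nCtrl = 100L,
                            seed = NULL) {
    genes <- rownames(x)
    sIn <- sort(intersect(sGenes, genes))   # order-invariant control draws
    gIn <- sort(intersect(g2mGenes, genes))
    if (length(sIn) < 5L || length(gIn) < 5L)
        stop("need at least 5 S genes and 5 G2M genes in the matrix (have ",
             length(sIn), " and ", length(gIn), ")")
    avg <- rowMeans(x)
    brk <- unique(stats::quantile(avg, probs = seq(0, 1, length.out =
                                                       nBins + 1L)))
    bin <- cut(avg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    names(bin) <- genes
    byBin <- split(genes, bin)
    scoreList <- function(lst) {
        ctrl <- unlist(lapply(lst, function(g)
            sample(byBin[[as.character(bin[g])]], nCtrl, replace = TRUE)),
            use.names = FALSE)
        colMeans(x[lst, , drop = FALSE]) -
            colMeans(x[ctrl, , drop = FALSE])
    }
    withSeed(seed, {
        s <- scoreList(sIn)
        g <- scoreList(gIn)
        data.frame(cell = colnames(x) %||% seq_len(ncol(x)),
                   s_score = unname(s), g2m_score = unname(g),
                   stringsAsFactors = FALSE)
    })
}

#' Assign cell-cycle phases
#'
#' A cell is called G1 when both module scores are negative; otherwise the
#' phase with the larger score wins (S on an exact tie).
#'
#' @param scores `data.frame` from [cellCycleScores()].
#' @return The input with a `phase` column (`G1`, `S` or `G2M`).
#' @export
assignPhase <- function(scores) {
    stopifnot(all(c("s_score", "g2m_score") %in% names(scores)))
    scores$phase <- ifelse(scores$s_score < 0 & scores$g2m_score < 0, "G1",
                           ifelse(scores$s_score >= scores$g2m_score,
                                  "S", "G2M"))
    scores
}

#' Phase fractions per population
#'
#' @param phase Character vector of phase calls.
#' @param population Population label per cell.
#' @return `data.frame` of per-population phase fractions (rows sum to 1).
#' @export
phaseFractions <- function(phase, population) {
    tab <- prop.table(table(population, phase), margin = 1L)
    as.data.frame.matrix(tab)
}
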