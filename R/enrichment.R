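# Core enrichment statistics: weighted-KS gene set enrichment, likelihood-
# weighted regulon enrichment, permutation nulls and NES.

# Closed-form weighted Kolmogorov-Smirnov enrichment statistic.
# absw: |score|^weight in ranking order (descending score); hitpos: sorted
# positions of set members in that order. The running sum increments by
# absw/sum(absw[hits]) at hits and decrements by 1/(N - nh) at misses; ES
# is the maximal signed deviation (negative branch wins ties).
.gseaStat <- function(absw, hitpos, N) {
    nh <- length(hitpos)
    if (nh == 0L) stop("no set gene in the signature universe")
    if (nh >= N) stop("gene set must be smaller than the universe")
    w <- absw[hitpos]
    W <- sum(w)
    winc <- if (W > 0) w / W else rep(1 / nh, nh)
    cumW <- cumsum(winc)
    missBefore <- (hitpos - seq_len(nh)) / (N - nh)
    top <- cumW - missBefore          # running sum at each hit
    bottom <- cumW - winc - missBefore  # running sum just before each hit
    maxP <- max(top, 0)
    minP <- min(bottom, 0)
    # exact +/- ties can occur structurally; resolve them deterministically
    # (negative branch) with a tolerance well below any real ES difference
    if (maxP + minP > 1e-9) maxP else minP
}

# Ranking order shared by all GSEA computations: descending score, ties
# broken lexicographically by gene id for determinism.
.gseaOrder <- function(sig) order(-sig, names(sig))

#' Gene set enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov statistic: genes are ranked by
#' descending signature score; walking down the ranking, the running sum
#' increases by `|score|^weight / sum(|score_set|^weight)` at set members
#' and decreases by `1/(N - n_set)` otherwise. The enrichment score (ES) is
#' the maximal signed deviation of this running sum from zero: positive
#' when the set concentrates at the top of the ranking, negative at the
#' bottom.
#'
#' @param sig Named numeric signature (unique gene ids, finite scores).
#' @param genes Character vector, the gene set; at least one member must be
#'   in the signature universe and the set must be smaller than it.
#' @param weight Exponent on `|score|` (1 = standard weighted GSEA).
#' @return Scalar ES in `[-1, 1]`.
#' @examples
#' sig <- stats::setNames(5:1, letters[1:5])
#' gseaES(sig, "a")   # top-ranked singleton: ES = 1
#' @export
gseaES <- function(sig, genes, weight = 1) {
    checkSignature(sig)
    ord <- .gseaOrder(sig)
    s <- sig[ord]
    .gseaStat(abs(s)^weight, which(names(s) %in% genes), length(s))
}

#' Regulon enrichment score
#'
#' Likelihood-weighted, mode-signed mean of the signature over a regulon's
#' targets: `ES = sum(likelihood * mode * sig[target]) / sum(likelihood)`.
#' Positive ES means the TF's activating targets rise (and repressed
#' targets fall) in the signature — the two-tailed reading of a weighted
#' regulatory network.
#'
#' @param sig Named numeric signature.
#' @param regulon A [Regulon-class].
#' @param minSize Minimum number of targets present in the signature
#'   universe; fewer is an error.
#' @return Scalar ES, linear in the signature.
#' @export
regulonES <- function(sig, regulon, minSize = 10L) {
    checkSignature(sig)
    stopifnot(is(regulon, "Regulon"))
    tg <- regulonTargets(regulon)
    tg <- tg[tg$target %in% names(sig), , drop = FALSE]
    if (nrow(tg) < minSize)
        stop("regulon '", regulonTF(regulon), "' has ", nrow(tg),
             " targets in the universe (< minSize = ", minSize, ")")
    sum(tg$likelihood * tg$mode * sig[tg$target]) / sum(tg$likelihood)
}

.esFor <- function(sig, obj, weight = 1, minSize = 10L) {
    if (is(obj, "Regulon")) regulonES(sig, obj, minSize = minSize)
    else gseaES(sig, obj, weight = weight)
}

#' Permutation null for an enrichment score
#'
#' Generates `nPerm` enrichment scores for one gene set or regulon under a
#' permutation null. `gene_shuffle` permutes the signature's gene labels
#' (randomizing which genes the set or network points at);
#' `sample_shuffle` recomputes the two-group signature after permuting the
#' group labels of the supplied expression matrix; `both` alternates the
#' two schemes permutation by permutation.
#'
#' @param sig Named numeric signature.
#' @param obj A [Regulon-class] or character gene set.
#' @param nPerm Number of permutations (>= 10).
#' @param scheme One of `"gene_shuffle"`, `"sample_shuffle"`, `"both"`.
#' @param seed Seed for the permutation stream.
#' @param exprs,cellsA,cellsB Log-normalized matrix and group columns;
#'   required for sample-based schemes (the signature must derive from
#'   this two-group contrast).
#' @param weight GSEA weight exponent (gene sets only).
#' @param minSize Minimum regulon size in the universe.
#' @return Numeric vector of `nPerm` null enrichment scores.
#' @export
permutationNull <- function(sig, obj, nPerm = 1000L,
                            scheme = c("gene_shuffle", "sample_shuffle",
                                       "both"),
                            seed = NULL, exprs = NULL, cellsA = NULL,
                            cellsB = NULL, weight = 1, minSize = 10L) {
    scheme <- match.arg(scheme)
    checkSignature(sig)
    if (nPerm < 10L) stop("nPerm must be at least 10")
    if (scheme != "gene_shuffle" &&
        (is.null(exprs) || is.null(cellsA) || is.null(cellsB)))
        stop("sample_shuffle requires 'exprs', 'cellsA' and 'cellsB'")
    nms <- names(sig)
    vals <- unname(sig)
    withSeed(seed, {
        vapply(seq_len(nPerm), function(i) {
            useSample <- scheme == "sample_shuffle" ||
                (scheme == "both" && i %% 2L == 0L)
            if (!useSample) {
                sperm <- stats::setNames(sample(vals), nms)
            } else {
                all <- c(cellsA, cellsB)
                idx <- sample(length(all))
                pa <- all[idx[seq_along(cellsA)]]
                pb <- all[idx[-seq_along(cellsA)]]
                de <- suppressWarnings(wilcoxonDE(exprs, pa, pb))
                sperm <- groupSignature(de)
            }
            .esFor(sperm, obj, weight = weight, minSize = minSize)
        }, numeric(1L))
    })
}

#' Normalized enrichment score and permutation p-value
#'
#' NES is the observed ES divided by the mean absolute permuted ES of the
#' same sign (falling back to the mean over all permutations when no
#' same-sign permutation exists); p is the add-one two-sided exceedance
#' `(1 + #\{|es_perm| >= |es_obs|\}) / (nPerm + 1)`.
#'
#' @param esObs Observed enrichment score.
#' @param null Numeric vector of permuted enrichment scores.
#' @return List with elements `nes` and `p`.
#' @export
nesFromNull <- function(esObs, null) {
    stopifnot(length(null) > 0L, is.finite(esObs), all(is.finite(null)))
    if (all(null == 0)) stop("degenerate null: all permuted scores are zero")
    same <- null[sign(null) == sign(esObs)]
    denom <- if (esObs == 0 || !length(same)) mean(abs(null))
             else mean(abs(same))
    list(nes = esObs / denom,
         p = (1 + sum(abs(null) >= abs(esObs))) / (length(null) + 1))
}

# One pool of gene-label permutations of the signature, shared across all
# regulons/sets of a batch run (deterministic per seed, ~20x cheaper than
# independent pools, and makes sign antisymmetry exact).
.permPool <- function(sig, nPerm, seed) {
    vals <- unname(sig)
    withSeed(seed, {
        P <- replicate(nPerm, sample(vals))
    })
    rownames(P) <- names(sig)
    P
}

#' Master regulator analysis
#'
#' Ranks transcription factors by the enrichment of their regulon in a
#' differential signature. Per TF: observed [regulonES()], a gene-label
#' permutation null (one shared seeded pool across TFs), NES and p from
#' [nesFromNull()], then Benjamini-Hochberg FDR over the per-TF p-values.
#' Regulons with fewer than `minSize` targets in the universe are skipped
#' with a warning.
#'
#' @param sig Named numeric signature (e.g. from [groupSignature()]).
#' @param regulons A [RegulonList-class].
#' @param nPerm Permutations per regulon.
#' @param seed Seed for the permutation pool.
#' @param minSize Minimum targets in the universe.
#' @return `data.frame` sorted by NES descending with columns `name`,
#'   `es`, `nes`, `p_value`, `fdr`, `n_perm`, `direction`.
#' @export
mra <- function(sig, regulons, nPerm = 1000L, seed = NULL, minSize = 10L) {
    checkSignature(sig)
    stopifnot(length(regulons) >= 1L)
    regs <- as.list(regulons)
    sizes <- vapply(regs, function(r)
        sum(regulonTargets(r)$target %in% names(sig)), integer(1L))
    if (any(sizes < minSize)) {
        warning("skipping ", sum(sizes < minSize),
                " regulon(s) below minSize: ",
                paste(names(regs)[sizes < minSize], collapse = ", "))
        regs <- regs[sizes >= minSize]
    }
    if (!length(regs)) stop("no eligible regulon")
    P <- .permPool(sig, nPerm, seed)
    rows <- lapply(regs, function(r) {
        tg <- regulonTargets(r)
        tg <- tg[tg$target %in% names(sig), , drop = FALSE]
        w <- tg$likelihood * tg$mode
        sl <- sum(tg$likelihood)
        es <- sum(w * sig[tg$target]) / sl
        null <- colSums(P[tg$target, , drop = FALSE] * w) / sl
        np <- nesFromNull(es, null)
        data.frame(name = regulonTF(r), es = es, nes = np$nes,
                   p_value = np$p, n_perm = nPerm,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- benjaminiHochberg(out$p_value)
    out$direction <- ifelse(out$es >= 0, 1L, -1L)
    out <- out[order(-out$nes, out$name),
               c("name", "es", "nes", "p_value", "fdr", "n_perm",
                 "direction")]
    rownames(out) <- NULL
    out
}

#' Batch GSEA with permutation NES
#'
#' [gseaES()] for every set in a collection against one signature, with a
#' shared seeded gene-label permutation null, NES, add-one p-values and
#' Benjamini-Hochberg FDR, sorted by NES descending (so the top and bottom
#' rows are the most up- and downregulated pathways).
#'
#' @param sig Named numeric signature.
#' @param sets Named list of character vectors (e.g. from [readGmt()]).
#' @param nPerm Permutations per set.
#' @param seed Seed for the permutation stream.
#' @param weight GSEA weight exponent.
#' @param minSize Minimum set size after intersection with the universe;
#'   smaller sets are skipped with a warning.
#' @return `data.frame` as in [mra()].
#' @export
gseaBatch <- function(sig, sets, nPerm = 1000L, seed = NULL, weight = 1,
                      minSize = 10L) {
    checkSignature(sig)
    stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
    ord <- .gseaOrder(sig)
    s <- sig[ord]
    N <- length(s)
    absw <- abs(s)^weight
    sizes <- vapply(sets, function(g) sum(names(s) %in% g), integer(1L))
    if (any(sizes < minSize)) {
        warning("skipping ", sum(sizes < minSize),
                " set(s) below minSize: ",
                paste(names(sets)[sizes < minSize], collapse = ", "))
        sets <- sets[sizes >= minSize]
        sizes <- sizes[sizes >= minSize]
    }
    if (!length(sets)) stop("no eligible gene set")
    rows <- withSeed(seed, lapply(seq_along(sets), function(k) {
        hitpos <- which(names(s) %in% sets[[k]])
        es <- .gseaStat(absw, hitpos, N)
        nh <- length(hitpos)
        null <- vapply(seq_len(nPerm), function(i)
            .gseaStat(absw, sort(sample.int(N, nh)), N), numeric(1L))
        np <- nesFromNull(es, null)
        data.frame(name = names(sets)[k], es = es, nes = np$nes,
                   p_value = np$p, n_perm = nPerm,
                   stringsAsFactors = FALSE)
    }))
    out <- do.call(rbind, rows)
    out$fdr <- benjaminiHochberg(out$p_value)
    out$direction <- ifelse(out$es >= 0, 1L, -1L)
    out <- out[order(-out$nes, out$name),
               c("name", "es", "nes", "p_value", "fdr", "n_perm",
                 "direction")]
    rownames(out) <- NULL
    out
}
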