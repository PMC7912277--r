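suppressPackageStartupMessages({
    library(SummarizedExperiment)
})

# Small configuration for fast unit tests; the acceptance suite uses the
# package defaults.
smallConfig <- function(seed = 1L, ...) {
    args <- list(nGenes = 400L, nTFs = 4L, targetsPerTF = 20L,
                 populations = data.frame(label = c("A", "B"),
                                          n_cells = c(40L, 40L),
                                          stringsAsFactors = FALSE),
                 meanReadsPerCell = 8000, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

simFixture <- function(config = smallConfig()) {
    truth <- makeTruth(config)
    sce <- simulateCounts(truth, config)
    list(config = config, truth = truth, sce = sce)
}

normalizedFixture <- function(config = smallConfig()) {
    fx <- simFixture(config)
    sce <- filterGenes(fx$sce)
    sce <- logNormalizeCounts(log10Tpm(tpmNormalize(sce)))
    fx$sce <- sce
    fx
}

randomSignature <- function(n = 50L, seed = 1L) {
    set.seed(seed)
    stats::setNames(stats::rnorm(n), sprintf("g%03d", seq_len(n)))
}

# Independent brute-force GSEA oracle: explicit running sum, step by step.
bruteGseaES <- function(sig, genes, weight = 1) {
    ord <- order(-sig, names(sig))
    s <- sig[ord]
    hit <- names(s) %in% genes
    nh <- sum(hit)
    denom <- sum(abs(s[hit])^weight)
    running <- 0
    best <- 0
    for (i in seq_along(s)) {
        running <- running + if (hit[i]) {
            if (denom > 0) abs(s[i])^weight / denom else 1 / nh
        } else -1 / (length(s) - nh)
        if (abs(running) > abs(best) + 1e-9 ||
            (abs(abs(running) - abs(best)) <= 1e-9 && running < best))
            best <- running
    }
    unname(best)
}

# Brute-force BH oracle: adj_i = min over the sorted tail of p_(j)*m/j.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- adj
    out
}

# Exact two-sided Wilcoxon p by enumerating every group-A assignment.
enumWilcoxP <- function(a, b) {
    x <- c(a, b)
    nA <- length(a)
    r <- rank(x)
    uObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    splits <- utils::combn(length(x), nA)
    uDist <- apply(splits, 2L, function(idx)
        sum(r[idx]) - nA * (nA + 1) / 2)
    min(1, 2 * min(mean(uDist <= uObs), mean(uDist >= uObs)))
}
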