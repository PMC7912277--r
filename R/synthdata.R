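#' Configure the synthetic scRNA-seq generator
#'
#' Builds a [SimConfig-class] describing two (or more) cell populations
#' whose transcriptomes differ through transcription-factor regulons,
#' unsynchronized cell-cycle structure, and a bimodal high-variance gene
#' group confined to one population (the behaviour metallothionein genes
#' show in cultured neuroblastoma lines). Counts are negative binomial with
#' lognormal library-size variation and logistic dropout.
#'
#' The default activity matrix activates the first five TFs (log-effect +2)
#' in the first population only, giving known master regulators to recover.
#' Default phase usage mimics an S-phase-heavy line versus a more evenly
#' cycling one.
#'
#' @param nGenes,nTFs,targetsPerTF Universe size and regulon structure;
#'   regulon target sets are disjoint, so `nTFs * targetsPerTF` must not
#'   exceed `nGenes`.
#' @param populations Data frame with columns `label` and `n_cells`.
#' @param activityMatrix `nTFs` x `nrow(populations)` matrix of log-scale
#'   shifts applied to each TF's targets (times target mode and
#'   likelihood). Default: +2 for TFs 1..5 in population 1.
#' @param cycleFraction Population x phase probability matrix over
#'   `G1, S, G2M`; rows sum to 1.
#' @param hvGroupSize,hvOnProb,hvShift Planted high-variance group: number
#'   of genes (confined to the last population), per-cell on-probability,
#'   and log-scale shift when on.
#' @param meanReadsPerCell,librarySigma Mean library size and the lognormal
#'   sigma of its cell-to-cell variation.
#' @param dispersion Negative binomial size parameter (larger = closer to
#'   Poisson).
#' @param dropoutMidpoint Mean count at which the logistic dropout retains
#'   a measurement with probability 1/2.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nGenes = 500, nTFs = 5, targetsPerTF = 20,
#'                  populations = data.frame(label = c("A", "B"),
#'                                           n_cells = c(50, 50)))
#' cfg
#' @export
simConfig <- function(nGenes = 2000L, nTFs = 20L, targetsPerTF = 50L,
                      populations = data.frame(
                          label = c("A", "B"), n_cells = c(300L, 300L),
                          stringsAsFactors = FALSE),
                      activityMatrix = NULL,
                      cycleFraction = NULL,
                      hvGroupSize = 30L, hvOnProb = 0.3, hvShift = 3,
                      meanReadsPerCell = 38000, librarySigma = 0.35,
                      dispersion = 1, dropoutMidpoint = 1,
                      seed = 1L) {
    np <- nrow(populations)
    if (is.null(activityMatrix)) {
        activityMatrix <- matrix(0, nTFs, np)
        activityMatrix[seq_len(min(5L, nTFs)), 1L] <- 2
    }
    if (is.null(cycleFraction)) {
        cycleFraction <- matrix(rep(c(1 / 3, 1 / 3, 1 / 3), np),
                                nrow = np, byrow = TRUE)
        if (np >= 1L) cycleFraction[1L, ] <- c(0.29, 0.45, 0.26)
        if (np >= 2L) cycleFraction[2L, ] <- c(0.20, 0.57, 0.23)
    }
    colnames(cycleFraction) <- c("G1", "S", "G2M")
    rownames(cycleFraction) <- populations$label
    rownames(activityMatrix) <- sprintf("TF%02d", seq_len(nTFs))
    colnames(activityMatrix) <- populations$label
    populations$n_cells <- as.integer(populations$n_cells)
    cfg <- new("SimConfig", nGenes = as.integer(nGenes),
               nTFs = as.integer(nTFs),
               targetsPerTF = as.integer(targetsPerTF),
               populations = populations, activityMatrix = activityMatrix,
               cycleFraction = cycleFraction,
               hvGroupSize = as.integer(hvGroupSize),
               hvOnProb = hvOnProb, hvShift = hvShift,
               meanReadsPerCell = meanReadsPerCell,
               librarySigma = librarySigma, dispersion = dispersion,
               dropoutMidpoint = dropoutMidpoint, seed = as.integer(seed))
    if (cfg@nTFs * cfg@targetsPerTF > cfg@nGenes)
        stop("configuration error: nTFs * targetsPerTF (", nTFs * targetsPerTF,
             ") exceeds nGenes (", nGenes, ")")
    cfg
}

#' Draw the simulation ground truth
#'
#' Decides everything upstream of count sampling: gene lengths (uniform in
#' 300--30000 bp), baseline log abundances, disjoint regulon target sets
#' with signed modes and likelihood weights, disjoint S and G2M phase
#' programs (40 genes each, +1 log-shift in their phase), the planted
#' high-variance group, and per-cell population and phase labels drawn from
#' the configured phase fractions.
#'
#' @param config A [SimConfig-class].
#' @return A [GroundTruth-class]; identical for identical configurations.
#' @examples
#' truth <- makeTruth(simConfig(nGenes = 500, nTFs = 5, targetsPerTF = 20))
#' truth
#' @export
makeTruth <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    nG <- config@nGenes
    withSeed(config@seed, {
        ids <- sprintf("G%05d", seq_len(nG))
        genes <- data.frame(gene_id = ids, symbol = ids,
                            length_bp = as.integer(round(
                                stats::runif(nG, 300, 30000))),
                            stringsAsFactors = FALSE)
        baseLogMean <- stats::setNames(stats::rnorm(nG, 0, 1), ids)

        pool <- sample(ids)
        take <- function(n) {
            if (n > length(pool))
                stop("configuration error: not enough genes for targets, ",
                     "phase programs and the high-variance group")
            out <- pool[seq_len(n)]
            pool <<- pool[-seq_len(n)]
            out
        }
        regs <- lapply(seq_len(config@nTFs), function(i) {
            tgt <- take(config@targetsPerTF)
            Regulon(sprintf("TF%02d", i), tgt,
                    mode = sample(c(1, -1), length(tgt), replace = TRUE,
                                  prob = c(0.7, 0.3)),
                    likelihood = stats::runif(length(tgt), 0.2, 1))
        })
        nPhase <- min(40L, max(0L, length(pool) %/% 3L))
        sGenes <- take(nPhase)
        g2mGenes <- take(nPhase)
        hvGenes <- take(min(config@hvGroupSize, length(pool)))
        # planted bimodal genes start from a low baseline so that the "on"
        # state creates the high-mean, high-variance pattern
        baseLogMean[hvGenes] <- baseLogMean[hvGenes] - 1

        pops <- config@populations
        cellLabels <- rep(pops$label, pops$n_cells)
        cycleLabels <- unlist(lapply(seq_len(nrow(pops)), function(k) {
            sample(colnames(config@cycleFraction), pops$n_cells[k],
                   replace = TRUE, prob = config@cycleFraction[k, ])
        }), use.names = FALSE)

        new("GroundTruth", genes = genes, baseLogMean = baseLogMean,
            regulons = RegulonList(regs),
            activityMatrix = config@activityMatrix,
            populations = pops, cycleFraction = config@cycleFraction,
            cellLabels = cellLabels, cycleLabels = cycleLabels,
            sGenes = sGenes, g2mGenes = g2mGenes, hvGenes = hvGenes,
            hvPopulation = pops$label[nrow(pops)],
            hvOnProb = config@hvOnProb, hvShift = config@hvShift)
    })
}

# Per-gene log mean for one (population, phase) before the softmax, without
# the stochastic high-variance on/off term.
.logMeanBase <- function(truth, pop, phase) {
    lm <- truth@baseLogMean
    k <- match(pop, truth@populations$label)
    for (r in as.list(truth@regulons)) {
        a <- truth@activityMatrix[regulonTF(r), k]
        if (a != 0) {
            tg <- regulonTargets(r)
            lm[tg$target] <- lm[tg$target] + a * tg$mode * tg$likelihood
        }
    }
    if (phase == "S") lm[truth@sGenes] <- lm[truth@sGenes] + 1
    if (phase == "G2M") lm[truth@g2mGenes] <- lm[truth@g2mGenes] + 1
    lm
}

#' Expected relative expression per population
#'
#' Pre-sampling expectation of each gene's relative abundance in each
#' population, averaging over the configured phase fractions and the
#' high-variance on/off mixture. Useful for checking effect directions
#' without sampling noise.
#'
#' @param truth A [GroundTruth-class].
#' @return Genes x populations matrix; columns sum to 1.
#' @export
expectedExpression <- function(truth) {
    stopifnot(is(truth, "GroundTruth"))
    pops <- truth@populations$label
    out <- sapply(pops, function(pop) {
        mix <- 0
        for (phase in colnames(truth@cycleFraction)) {
            lm <- .logMeanBase(truth, pop, phase)
            w <- exp(lm - max(lm))
            if (pop == truth@hvPopulation && length(truth@hvGenes))
                w[truth@hvGenes] <- w[truth@hvGenes] *
                    ((1 - truth@hvOnProb) + truth@hvOnProb *
                         exp(truth@hvShift))
            mix <- mix + truth@cycleFraction[pop, phase] * w / sum(w)
        }
        mix
    })
    rownames(out) <- truth@genes$gene_id
    out
}

#' Simulate single-cell counts
#'
#' Samples a gene x cell count matrix from the ground truth. For each cell,
#' gene means are the softmax of `baseLogMean` plus the regulon activity
#' effects of its population, the phase program shift of its phase, and (in
#' the high-variance population) a per-cell Bernoulli on/off shift for the
#' planted group; the mean vector is scaled by a lognormal library size and
#' counts are negative binomial, thinned by multiplicative logistic dropout
#' with midpoint `dropoutMidpoint`.
#'
#' @param truth A [GroundTruth-class] from [makeTruth()].
#' @param config The matching [SimConfig-class].
#' @param seed Seed for the count draw; defaults to `config@seed + 1` so
#'   truth and counts use distinct streams.
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts`, rowData `gene_id`/`symbol`/`length_bp`, and colData
#'   `barcode`, `population`, `phase`, `total_reads`.
#' @examples
#' cfg <- simConfig(nGenes = 300, nTFs = 3, targetsPerTF = 20,
#'                  populations = data.frame(label = c("A", "B"),
#'                                           n_cells = c(30, 30)))
#' sce <- simulateCounts(makeTruth(cfg), cfg)
#' sce
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame
#' @export
simulateCounts <- function(truth, config, seed = config@seed + 1L) {
    stopifnot(is(truth, "GroundTruth"), is(config, "SimConfig"))
    if (nrow(truth@genes) != config@nGenes)
        stop("truth and config disagree on the number of genes")
    nCells <- length(truth@cellLabels)
    nG <- config@nGenes
    ids <- truth@genes$gene_id
    hvIdx <- match(truth@hvGenes, ids)

    # cache the deterministic part of the log mean per (population, phase)
    keys <- unique(paste(truth@cellLabels, truth@cycleLabels, sep = "\r"))
    baseCache <- lapply(keys, function(k) {
        kv <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        .logMeanBase(truth, kv[1L], kv[2L])
    })
    names(baseCache) <- keys

    counts <- matrix(0L, nG, nCells)
    withSeed(seed, {
        lib <- stats::rlnorm(nCells,
                             meanlog = log(config@meanReadsPerCell) -
                                 config@librarySigma^2 / 2,
                             sdlog = config@librarySigma)
        for (c in seq_len(nCells)) {
            lm <- baseCache[[paste(truth@cellLabels[c], truth@cycleLabels[c],
                                   sep = "\r")]]
            if (truth@cellLabels[c] == truth@hvPopulation &&
                length(hvIdx)) {
                on <- stats::rbinom(length(hvIdx), 1L, truth@hvOnProb) == 1L
                lm[hvIdx[on]] <- lm[hvIdx[on]] + truth@hvShift
            }
            mu <- softmax(lm) * lib[c]
            keep <- stats::rbinom(nG, 1L, mu / (mu + config@dropoutMidpoint))
            counts[, c] <- as.integer(
                stats::rnbinom(nG, size = config@dispersion, mu = mu) * keep)
        }
    })
    dimnames(counts) <- list(ids, sprintf("CELL%05d", seq_len(nCells)))
    SingleCellExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(truth@genes, row.names = ids),
        colData = DataFrame(barcode = colnames(counts),
                            population = truth@cellLabels,
                            phase = truth@cycleLabels,
                            total_reads = colSums(counts),
                            row.names = colnames(counts)))
}

#' Simulate matched bulk RNA-seq profiles
#'
#' Produces TPM-scaled bulk expression columns per population from the same
#' expected abundances that drive the single-cell simulation, but without
#' single-cell dropout. Replicates add mild lognormal gene-level noise.
#'
#' @param truth A [GroundTruth-class].
#' @param nReplicates Bulk replicates per population; 0 gives an empty
#'   panel.
#' @param noiseSd Lognormal sd of replicate noise on the expected profile.
#' @param seed Seed for replicate noise.
#' @return Genes x (populations x replicates) matrix; every column sums to
#'   1e6 (TPM).
#' @export
simulateBulk <- function(truth, nReplicates = 3L, noiseSd = 0.1,
                         seed = NULL) {
    stopifnot(is(truth, "GroundTruth"), nReplicates >= 0L)
    ids <- truth@genes$gene_id
    lenKb <- truth@genes$length_bp / 1000
    ee <- expectedExpression(truth)
    pops <- colnames(ee)
    out <- matrix(0, length(ids), nrow(truth@populations) * nReplicates)
    rownames(out) <- ids
    if (nReplicates == 0L) {
        colnames(out) <- character(0)
        return(out)
    }
    cn <- character(ncol(out))
    withSeed(seed, {
        j <- 0L
        for (pop in pops) {
            for (r in seq_len(nReplicates)) {
                j <- j + 1L
                a <- ee[, pop] * exp(stats::rnorm(length(ids), 0, noiseSd))
                rate <- a / lenKb
                out[, j] <- rate / sum(rate) * 1e6
                cn[j] <- sprintf("%s_rep%d", pop, r)
            }
        }
    })
    colnames(out) <- cn
    out
}

#' Gene sets implied by the ground truth
#'
#' Returns the regulon target sets plus the S and G2M phase programs as a
#' named list of gene-id vectors, usable directly with [gseaBatch()] or
#' written with [writeGmt()].
#'
#' @param truth A [GroundTruth-class].
#' @return Named list of character vectors.
#' @export
truthGeneSets <- function(truth) {
    stopifnot(is(truth, "GroundTruth"))
    sets <- lapply(as.list(truth@regulons),
                   function(r) regulonTargets(r)$target)
    names(sets) <- paste0("TARGETS_", names(truth@regulons))
    sets$PHASE_S <- truth@sGenes
    sets$PHASE_G2M <- truth@g2mGenes
    if (length(truth@hvGenes)) sets$HV_GROUP <- truth@hvGenes
    sets
}
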