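#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

#' Regulon: a transcription factor with weighted, signed targets
#'
#' A regulon is a transcription factor (TF) together with its inferred target
#' genes. Each target carries a \emph{mode} (the sign and strength of
#' regulation, in \code{[-1, 1]}) and a \emph{likelihood} (a confidence
#' weight in \code{(0, 1]}). Regulons are the unit of master regulator
#' analysis: the enrichment of a regulon's targets in a differential
#' signature measures the inferred activity change of its TF.
#'
#' @slot tf Character scalar, the transcription factor name.
#' @slot targets A \code{data.frame} with columns \code{target} (character),
#'   \code{mode} (numeric in \code{[-1, 1]}) and \code{likelihood} (numeric
#'   in \code{(0, 1]}); target names are unique and never equal to the TF.
#'
#' @seealso [regulonES()], [mra()], [readRegulons()]
#' @export
setClass("Regulon", slots = c(tf = "character", targets = "data.frame"))

setValidity("Regulon", function(object) {
    tg <- object@targets
    msg <- character()
    if (length(object@tf) != 1L || is.na(object@tf) || !nzchar(object@tf))
        msg <- c(msg, "'tf' must be a single non-empty string")
    need <- c("target", "mode", "likelihood")
    if (!all(need %in% names(tg)))
        return(sprintf("'targets' must have columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(tg$target))
        msg <- c(msg, "duplicated target genes")
    if (length(object@tf) == 1L && object@tf %in% tg$target)
        msg <- c(msg, "self-edge: tf appears among its own targets")
    if (any(!is.finite(tg$mode)) || any(tg$mode < -1) || any(tg$mode > 1))
        msg <- c(msg, "'mode' must lie in [-1, 1]")
    if (any(!is.finite(tg$likelihood)) || any(tg$likelihood <= 0) ||
        any(tg$likelihood > 1))
        msg <- c(msg, "'likelihood' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a Regulon
#'
#' @param tf TF name.
#' @param target Character vector of target gene identifiers.
#' @param mode Numeric vector in \code{[-1, 1]}, recycled to
#'   \code{length(target)}.
#' @param likelihood Numeric vector in \code{(0, 1]}, recycled likewise.
#' @return A [Regulon-class] object.
#' @examples
#' Regulon("TF1", c("G1", "G2"), mode = c(1, -1), likelihood = c(1, 0.5))
#' @export
Regulon <- function(tf, target, mode = 1, likelihood = 1) {
    tg <- data.frame(target = as.character(target),
                     mode = rep_len(as.numeric(mode), length(target)),
                     likelihood = rep_len(as.numeric(likelihood),
                                          length(target)),
                     stringsAsFactors = FALSE)
    new("Regulon", tf = as.character(tf), targets = tg)
}

#' @describeIn Regulon TF name accessor.
#' @param x A \code{Regulon}.
#' @export
regulonTF <- function(x) x@tf

#' @describeIn Regulon Target table accessor (columns \code{target},
#'   \code{mode}, \code{likelihood}).
#' @export
regulonTargets <- function(x) x@targets

setMethod("show", "Regulon", function(object) {
    cat(sprintf("Regulon '%s' with %d targets\n", object@tf,
                nrow(object@targets)))
    cat(sprintf("  modes: %d activating, %d repressing\n",
                sum(object@targets$mode >= 0), sum(object@targets$mode < 0)))
})

#' List of regulons
#'
#' A \code{SimpleList} whose elements are [Regulon-class] objects, named by
#' TF. This is the container read from regulon TSV files and consumed by
#' [mra()] and [scActivity()].
#'
#' @export
setClass("RegulonList", contains = "SimpleList",
         prototype = prototype(elementType = "Regulon"))

#' Construct a RegulonList
#'
#' @param ... \code{Regulon} objects, or a single list of them.
#' @return A [RegulonList-class] named by TF.
#' @export
RegulonList <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1L]]) &&
        !is(args[[1L]], "Regulon"))
        args <- args[[1L]]
    stopifnot(all(vapply(args, is, logical(1L), "Regulon")))
    names(args) <- vapply(args, regulonTF, character(1L))
    new("RegulonList", SimpleList(args))
}

setMethod("show", "RegulonList", function(object) {
    cat(sprintf("RegulonList of %d regulons (%s)\n", length(object),
                paste(utils::head(names(object), 5L), collapse = ", ")))
})

#' Simulation configuration
#'
#' Parameters of the synthetic scRNA-seq generator. Defaults describe two
#' unsynchronized cell populations with regulon-driven expression
#' differences, distinct cell-cycle phase usage, a planted high-variance
#' gene group confined to one population, and library sizes varying
#' lognormally around a target depth. See [simConfig()].
#'
#' @slot nGenes,nTFs,targetsPerTF Positive integer counts.
#' @slot populations \code{data.frame} with columns \code{label},
#'   \code{n_cells}.
#' @slot activityMatrix TF x population matrix of log-scale activity shifts
#'   applied to each TF's targets (signed by target mode, scaled by
#'   likelihood).
#' @slot cycleFraction population x phase (\code{G1,S,G2M}) matrix of phase
#'   probabilities; rows sum to 1.
#' @slot hvGroupSize Number of high-variance genes planted in
#'   \code{hvPopulation}-th population.
#' @slot hvOnProb,hvShift Bernoulli on-probability and log-scale shift of
#'   the planted bimodal high-variance genes.
#' @slot meanReadsPerCell Target mean library size (reads per cell).
#' @slot librarySigma Lognormal sigma of the library-size distribution.
#' @slot dispersion Negative binomial size parameter.
#' @slot dropoutMidpoint Mean count at which the logistic dropout keeps a
#'   gene with probability 1/2.
#' @slot seed Integer seed for all simulator randomness.
#' @export
setClass("SimConfig", slots = c(
    nGenes = "integer", nTFs = "integer", targetsPerTF = "integer",
    populations = "data.frame", activityMatrix = "matrix",
    cycleFraction = "matrix", hvGroupSize = "integer",
    hvOnProb = "numeric", hvShift = "numeric",
    meanReadsPerCell = "numeric", librarySigma = "numeric",
    dispersion = "numeric", dropoutMidpoint = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(nGenes = object@nGenes, nTFs = object@nTFs,
             targetsPerTF = object@targetsPerTF)
    if (any(cnt <= 0L)) msg <- c(msg, "counts must be positive")
    if (object@hvGroupSize < 0L) msg <- c(msg, "hvGroupSize must be >= 0")
    if (!all(c("label", "n_cells") %in% names(object@populations)))
        msg <- c(msg, "populations needs columns label, n_cells")
    else if (any(object@populations$n_cells <= 0L))
        msg <- c(msg, "population sizes must be positive")
    np <- nrow(object@populations)
    if (!identical(dim(object@activityMatrix),
                   c(object@nTFs, np)))
        msg <- c(msg, "activityMatrix must be nTFs x nPopulations")
    if (any(!is.finite(object@activityMatrix)))
        msg <- c(msg, "activityMatrix must be finite")
    if (!identical(dim(object@cycleFraction), c(np, 3L)))
        msg <- c(msg, "cycleFraction must be nPopulations x 3 (G1,S,G2M)")
    else if (any(abs(rowSums(object@cycleFraction) - 1) > 1e-8) ||
             any(object@cycleFraction < 0))
        msg <- c(msg, "cycleFraction rows must be probabilities summing to 1")
    pos <- c(object@meanReadsPerCell, object@dispersion,
             object@dropoutMidpoint)
    if (any(!is.finite(pos)) || any(pos <= 0))
        msg <- c(msg, paste("meanReadsPerCell, dispersion and",
                            "dropoutMidpoint must be positive"))
    if (object@librarySigma < 0) msg <- c(msg, "librarySigma must be >= 0")
    if (object@hvOnProb < 0 || object@hvOnProb > 1)
        msg <- c(msg, "hvOnProb must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Everything the generator decided before sampling counts: the gene
#' universe with lengths, baseline log means, the regulons and the TF
#' activity matrix, per-cell population and cell-cycle phase labels, the
#' phase gene programs and the planted high-variance gene group. Recovery
#' tests compare pipeline output against these fields.
#'
#' @slot genes \code{data.frame} with \code{gene_id}, \code{symbol},
#'   \code{length_bp}.
#' @slot baseLogMean Named numeric, baseline log relative abundance.
#' @slot regulons A [RegulonList-class].
#' @slot activityMatrix TF x population log-scale effects.
#' @slot populations,cycleFraction Copied from the configuration.
#' @slot cellLabels,cycleLabels Per-cell population and phase.
#' @slot sGenes,g2mGenes Cell-cycle phase program gene ids (disjoint).
#' @slot hvGenes,hvPopulation The planted high-variance genes and the
#'   population label they are confined to.
#' @slot hvOnProb,hvShift High-variance group parameters.
#' @export
setClass("GroundTruth", slots = c(
    genes = "data.frame", baseLogMean = "numeric", regulons = "RegulonList",
    activityMatrix = "matrix", populations = "data.frame",
    cycleFraction = "matrix", cellLabels = "character",
    cycleLabels = "character", sGenes = "character", g2mGenes = "character",
    hvGenes = "character", hvPopulation = "character",
    hvOnProb = "numeric", hvShift = "numeric"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    ids <- object@genes$gene_id
    tgt <- unlist(lapply(object@regulons,
                         function(r) regulonTargets(r)$target))
    if (!all(tgt %in% ids))
        msg <- c(msg, "regulon targets outside the gene universe")
    if (length(intersect(object@sGenes, object@g2mGenes)))
        msg <- c(msg, "S and G2M gene programs must be disjoint")
    if (length(object@cellLabels) != length(object@cycleLabels))
        msg <- c(msg, "cellLabels and cycleLabels lengths differ")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(paste0("GroundTruth: %d genes, %d regulons, %d cells ",
                       "(%s)\n"),
                nrow(object@genes), length(object@regulons),
                length(object@cellLabels),
                paste(sprintf("%s=%d", object@populations$label,
                              object@populations$n_cells), collapse = ", ")))
    cat(sprintf("  phase programs: %d S genes, %d G2M genes; %d HV genes in %s\n",
                length(object@sGenes), length(object@g2mGenes),
                length(object@hvGenes), object@hvPopulation))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: %d genes, %d TFs x %d targets, ",
                       "populations %s\n"),
                object@nGenes, object@nTFs, object@targetsPerTF,
                paste(sprintf("%s=%d", object@populations$label,
                              object@populations$n_cells), collapse = ", ")))
    cat(sprintf("  reads/cell ~ %g (sigma %g), NB size %g, dropout mid %g, seed %d\n",
                object@meanReadsPerCell, object@librarySigma,
                object@dispersion, object@dropoutMidpoint, object@seed))
})
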