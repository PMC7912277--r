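#' Run the full synthetic analysis pipeline
#'
#' End-to-end workflow on simulated data: draw ground truth and counts,
#' write the raw dataset (10x-style triplet, annotation, regulon TSV, GMT,
#' truth JSON), filter genes, normalize (TPM, log10 TPM, log-normalized),
#' compute per-gene statistics, two-group differential expression and the
#' signed-z signature, master regulator analysis and batch GSEA, per-cell
#' regulon activity, cell-cycle scores and phase assignment, and
#' pseudobulk-to-bulk matching. All tables are written as CSV and a JSON
#' manifest records versions, seed, parameters and MD5 checksums of every
#' output, so a run can be reproduced bit for bit.
#'
#' @param outdir Output directory (created).
#' @param config A [SimConfig-class]; its seed drives all randomness.
#' @param nPerm Permutations for group-level MRA and GSEA.
#' @param scNPerm Permutations per object for per-cell activity.
#' @param bulkReplicates Bulk replicates per population.
#' @param minCells Gene filter threshold.
#' @return Invisibly, a list with all in-memory results (`sce`, `stats`,
#'   `de`, `signature`, `mra`, `gsea`, `activity`, `cellcycle`,
#'   `phaseFractions`, `bulk`, `bulkMatch`, `manifest`).
#' @importFrom SummarizedExperiment assay colData
#' @export
runPipeline <- function(outdir, config = simConfig(), nPerm = 1000L,
                        scNPerm = 100L, bulkReplicates = 3L,
                        minCells = 3L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- config@seed
    truth <- makeTruth(config)
    sce <- simulateCounts(truth, config)

    writeMtx(sce, file.path(outdir, "raw"))
    utils::write.csv(as.data.frame(colData(sce)),
                     file.path(outdir, "annotation.csv"), row.names = FALSE)
    writeRegulons(truth@regulons, file.path(outdir, "regulons.tsv"))
    writeGmt(truthGeneSets(truth), file.path(outdir, "gene_sets.gmt"))
    writeTruthJson(truth, file.path(outdir, "ground_truth.json"))

    sce <- filterGenes(sce, minCells = minCells)
    sce <- log10Tpm(tpmNormalize(sce))
    sce <- logNormalizeCounts(sce)
    counts <- assay(sce, "counts")
    logtpm <- assay(sce, "logtpm")
    lognorm <- assay(sce, "lognorm")
    pop <- colData(sce)$population
    pops <- truth@populations$label

    stats <- geneStats(logtpm, counts)
    utils::write.csv(stats, file.path(outdir, "gene_stats.csv"),
                     row.names = FALSE)

    cellsA <- colnames(sce)[pop == pops[1L]]
    cellsB <- colnames(sce)[pop == pops[2L]]
    de <- suppressWarnings(wilcoxonDE(lognorm, cellsA, cellsB))
    utils::write.csv(de, file.path(outdir, "de.csv"), row.names = FALSE)
    sig <- groupSignature(de)

    mraRes <- suppressWarnings(mra(sig, truth@regulons, nPerm = nPerm,
                                   seed = seed + 10L))
    utils::write.csv(mraRes, file.path(outdir, "mra.csv"),
                     row.names = FALSE)
    gseaRes <- suppressWarnings(gseaBatch(sig, truthGeneSets(truth),
                                          nPerm = nPerm,
                                          seed = seed + 11L))
    utils::write.csv(gseaRes, file.path(outdir, "gsea.csv"),
                     row.names = FALSE)

    act <- suppressWarnings(scActivity(cellSignatures(logtpm),
                                       truth@regulons, nPerm = scNPerm,
                                       seed = seed + 12L))
    utils::write.csv(data.frame(cell = rownames(act), act,
                                check.names = FALSE),
                     file.path(outdir, "activity.csv"), row.names = FALSE)

    cc <- assignPhase(cellCycleScores(lognorm, truth@sGenes,
                                      truth@g2mGenes, seed = seed + 13L))
    utils::write.csv(cc, file.path(outdir, "cellcycle.csv"),
                     row.names = FALSE)
    pf <- phaseFractions(cc$phase, pop)
    utils::write.csv(data.frame(population = rownames(pf), pf,
                                check.names = FALSE),
                     file.path(outdir, "phase_fractions.csv"),
                     row.names = FALSE)

    bulk <- simulateBulk(truth, nReplicates = bulkReplicates,
                         seed = seed + 14L)
    utils::write.csv(data.frame(gene = rownames(bulk), bulk,
                                check.names = FALSE),
                     file.path(outdir, "bulk_panel.csv"), row.names = FALSE)
    tpmMat <- assay(sce, "tpm")
    pb <- sapply(pops, function(p)
        pseudobulk(tpmMat[, pop == p, drop = FALSE]))
    colnames(pb) <- paste0("pseudo_", pops)
    bm <- matchBulk(pb, bulk)
    utils::write.csv(bm, file.path(outdir, "bulk_correlations.csv"),
                     row.names = FALSE)

    outputs <- c("gene_stats.csv", "de.csv", "mra.csv", "gsea.csv",
                 "activity.csv", "cellcycle.csv", "phase_fractions.csv",
                 "bulk_panel.csv", "bulk_correlations.csv",
                 "annotation.csv", "regulons.tsv", "gene_sets.gmt",
                 "ground_truth.json")
    manifest <- list(
        package = "scregulon",
        version = as.character(utils::packageVersion("scregulon")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = seed,
        parameters = list(
            n_genes = config@nGenes, n_tfs = config@nTFs,
            targets_per_tf = config@targetsPerTF,
            populations = config@populations,
            mean_reads_per_cell = config@meanReadsPerCell,
            library_sigma = config@librarySigma,
            dispersion = config@dispersion,
            dropout_midpoint = config@dropoutMidpoint,
            n_perm = nPerm, sc_n_perm = scNPerm,
            bulk_replicates = bulkReplicates, min_cells = minCells),
        checksums = as.list(tools::md5sum(file.path(outdir, outputs))))
    names(manifest$checksums) <- outputs
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(sce = sce, truth = truth, stats = stats, de = de,
                   signature = sig, mra = mraRes, gsea = gseaRes,
                   activity = act, cellcycle = cc, phaseFractions = pf,
                   bulk = bulk, bulkMatch = bm, manifest = manifest))
}
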