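test_that("generator is deterministic given the configuration seed", {
    cfg <- smallConfig(seed = 7L)
    t1 <- makeTruth(cfg)
    t2 <- makeTruth(cfg)
    expect_identical(t1, t2)
    s1 <- simulateCounts(t1, cfg)
    s2 <- simulateCounts(t2, cfg)
    expect_identical(assay(s1, "counts"), assay(s2, "counts"))
    expect_identical(simulateBulk(t1, seed = 3L), simulateBulk(t2, seed = 3L))
})

test_that("ground truth honours the construction contract", {
    cfg <- smallConfig(nGenes = 500L, nTFs = 5L, targetsPerTF = 50L)
    truth <- makeTruth(cfg)
    expect_length(truth@regulons, 5L)
    ids <- truth@genes$gene_id
    for (r in as.list(truth@regulons)) {
        tg <- regulonTargets(r)
        expect_equal(nrow(tg), 50L)
        expect_true(all(tg$target %in% ids))
        expect_true(all(tg$mode %in% c(-1, 1)))
        expect_true(all(tg$likelihood > 0 & tg$likelihood <= 1))
    }
    expect_length(intersect(truth@sGenes, truth@g2mGenes), 0L)
    expect_true(all(truth@genes$length_bp >= 300 &
                        truth@genes$length_bp <= 30000))
})

test_that("over-subscribed regulon structure is a configuration error", {
    expect_error(smallConfig(nGenes = 90L, nTFs = 5L, targetsPerTF = 20L),
                 "configuration error")
})

test_that("zero activity gives identical expected expression across populations", {
    cfg <- smallConfig(activityMatrix = matrix(0, 4, 2), hvGroupSize = 0L,
                       cycleFraction = matrix(rep(c(0.3, 0.45, 0.25), 2),
                                              2, byrow = TRUE))
    ee <- expectedExpression(makeTruth(cfg))
    expect_equal(ee[, 1], ee[, 2])
})

test_that("counts are non-negative integers and annotation matches columns", {
    fx <- simFixture()
    m <- assay(fx$sce, "counts")
    expect_true(all(m >= 0))
    expect_true(is.integer(m))
    expect_equal(nrow(colData(fx$sce)), ncol(m))
    expect_identical(colData(fx$sce)$population, fx$truth@cellLabels)
    expect_identical(colData(fx$sce)$phase, fx$truth@cycleLabels)
    expect_equal(unname(colData(fx$sce)$total_reads), unname(colSums(m)))
})

test_that("dispersion -> infinity approaches the Poisson variance/mean ratio", {
    cfg <- smallConfig(nGenes = 300L, nTFs = 2L, targetsPerTF = 10L,
                       populations = data.frame(label = "A",
                                                n_cells = 250L),
                       activityMatrix = matrix(0, 2, 1),
                       cycleFraction = matrix(c(1, 0, 0), 1),
                       hvGroupSize = 0L,
                       dispersion = 1e6, librarySigma = 0,
                       dropoutMidpoint = 1e-9)
    fx <- simFixture(cfg)
    m <- assay(fx$sce, "counts")
    mu <- rowMeans(m)
    ratio <- apply(m, 1L, stats::var) / mu
    keep <- mu > 2   # expressed genes, where dropout is negligible
    expect_gt(sum(keep), 50L)
    expect_lt(abs(median(ratio[keep]) - 1), 0.1)
    expect_lt(abs(mean(ratio[keep]) - 1), 0.1)
})

test_that("raising a TF's activity raises its activating targets' expectation", {
    lo <- smallConfig(activityMatrix = matrix(0, 4, 2))
    hi <- smallConfig(activityMatrix = rbind(c(2, 0), matrix(0, 3, 2)))
    eLo <- expectedExpression(makeTruth(lo))
    eHi <- expectedExpression(makeTruth(hi))  # same seed: same regulons
    tg <- regulonTargets(makeTruth(lo)@regulons[["TF01"]])
    up <- tg$target[tg$mode > 0]
    expect_true(all(eHi[up, "A"] > eLo[up, "A"]))
    expect_equal(eHi[, "B"], eLo[, "B"])
})

test_that("bulk panel is TPM-scaled and degenerate replicate counts work", {
    truth <- makeTruth(smallConfig())
    bulk <- simulateBulk(truth, nReplicates = 2L, seed = 5L)
    expect_equal(ncol(bulk), 4L)
    expect_equal(unname(colSums(bulk)), rep(1e6, 4L), tolerance = 1e-6)
    empty <- simulateBulk(truth, nReplicates = 0L)
    expect_equal(ncol(empty), 0L)
})
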