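test_that("cell signatures are z-scores with population sd", {
    x <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("c1", "c2")))
    z <- cellSignatures(x)
    expect_equal(unname(z[1, ]), c(-1, 1))

    set.seed(41)
    x2 <- matrix(rnorm(50 * 8), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
    x2 <- rbind(x2, flat = rep(1, 8))
    z2 <- cellSignatures(x2)
    expect_false("flat" %in% rownames(z2))   # zero-variance genes dropped
    expect_true(all(abs(rowSums(z2)) < 1e-6 * ncol(z2)))
    expect_error(cellSignatures(x2[, 1, drop = FALSE]), "at least 2")
})

test_that("a zero signature yields zero activity in every object", {
    set.seed(42)
    z <- matrix(rnorm(80 * 5), 80, 5,
                dimnames = list(sprintf("g%02d", 1:80),
                                paste0("c", 1:5)))
    z[, 3] <- 0
    rl <- RegulonList(Regulon("T1", rownames(z)[1:15]),
                      Regulon("T2", rownames(z)[16:30]))
    act <- scActivity(z, rl, nPerm = 50L, seed = 1L)
    expect_equal(unname(act["c3", ]), c(0, 0))
    expect_identical(colnames(act), c("T1", "T2"))
})

test_that("activity is antisymmetric when all signatures flip sign", {
    set.seed(43)
    z <- matrix(rnorm(60 * 6), 60, 6,
                dimnames = list(sprintf("g%02d", 1:60), paste0("c", 1:6)))
    rl <- RegulonList(Regulon("T1", rownames(z)[1:12],
                              mode = sample(c(1, -1), 12, TRUE)))
    a1 <- scActivity(z, rl, nPerm = 100L, seed = 9L)
    a2 <- scActivity(-z, rl, nPerm = 100L, seed = 9L)
    expect_equal(a2, -a1, tolerance = 1e-12)
})

test_that("population-restricted activity separates populations", {
    fx <- normalizedFixture(smallConfig(seed = 3L))
    pop <- colData(fx$sce)$population
    z <- cellSignatures(assay(fx$sce, "logtpm"))
    act <- suppressWarnings(scActivity(z, fx$truth@regulons, nPerm = 100L,
                                       seed = 5L))
    active <- rownames(fx$config@activityMatrix)[
        fx$config@activityMatrix[, "A"] != 0]
    for (tf in active) {
        w <- stats::t.test(act[pop == "A", tf], act[pop == "B", tf])
        expect_lt(w$p.value, 0.01)
        expect_gt(mean(act[pop == "A", tf]), mean(act[pop == "B", tf]))
    }
})

test_that("per-cell gene-set activity runs within budget on the small fixture", {
    set.seed(44)
    z <- matrix(rnorm(200 * 50), 200, 50,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
    sets <- lapply(1:5, function(i) sample(rownames(z), 20))
    names(sets) <- paste0("S", 1:5)
    elapsed <- system.time(
        act <- scActivity(z, sets, nPerm = 100L, seed = 2L))["elapsed"]
    expect_lt(elapsed, 10)
    expect_equal(dim(act), c(50L, 5L))
    expect_true(all(is.finite(act)))
})

test_that("module scores cancel against expression-matched controls", {
    # constant-across-cells expression: every control shares its list
    # gene's bin, so scores shrink to within a bin's width of zero
    set.seed(45)
    vals <- sort(runif(120, 0, 2))
    x <- matrix(rep(vals, 6), 120, 6,
                dimnames = list(sprintf("g%03d", 1:120), paste0("c", 1:6)))
    sList <- rownames(x)[seq(10, 110, by = 20)]
    gList <- rownames(x)[seq(15, 115, by = 20)]
    sc <- cellCycleScores(x, sList, gList, seed = 6L)
    expect_lt(max(abs(sc$s_score)), 0.08)
    expect_lt(max(abs(sc$g2m_score)), 0.08)

    # invariant to gene order permutation of the input lists
    sc2 <- cellCycleScores(x, rev(sList), rev(gList), seed = 6L)
    expect_equal(sc2$s_score, sc$s_score)
    expect_error(cellCycleScores(x, sList[1:3], gList), "at least 5")
})

test_that("phase calls follow the G1 / argmax rule and fractions sum to 1", {
    sc <- data.frame(cell = c("a", "b", "c", "d"),
                     s_score = c(-0.2, 0.5, 0.1, 0.2),
                     g2m_score = c(-0.1, 0.1, 0.5, 0.2))
    ph <- assignPhase(sc)
    expect_identical(ph$phase, c("G1", "S", "G2M", "S"))
    pf <- phaseFractions(ph$phase, c("P1", "P1", "P2", "P2"))
    expect_equal(unname(rowSums(pf)), c(1, 1))
})

test_that("simulated S-phase cells score S above G2M", {
    fx <- normalizedFixture(smallConfig(seed = 5L))
    ln <- assay(fx$sce, "lognorm")
    sc <- cellCycleScores(ln, fx$truth@sGenes, fx$truth@g2mGenes,
                          seed = 8L)
    inS <- colData(fx$sce)$phase == "S"
    expect_gt(mean(sc$s_score[inS] > sc$g2m_score[inS]), 0.9)
})
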