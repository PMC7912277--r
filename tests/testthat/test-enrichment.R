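test_that("gseaES equals the brute-force running-sum oracle", {
    sig <- randomSignature(12, seed = 5)
    set.seed(6)
    for (i in 1:30) {
        genes <- sample(names(sig), 4)
        expect_equal(gseaES(sig, genes), bruteGseaES(sig, genes),
                     tolerance = 1e-12)
    }
    # weight 0 (unweighted KS) goes through the zero-denominator-safe path
    expect_equal(gseaES(sig, names(sig)[1:3], weight = 0),
                 bruteGseaES(sig, names(sig)[1:3], weight = 0),
                 tolerance = 1e-12)
})

test_that("extreme singletons pin the ES sign", {
    sig <- randomSignature(20, seed = 7)
    top <- names(sig)[which.max(sig)]
    bottom <- names(sig)[which.min(sig)]
    expect_equal(gseaES(sig, top), 1)
    expect_lt(gseaES(sig, bottom), 0)
    expect_error(gseaES(sig, c("absent1", "absent2")), "universe")
    expect_error(gseaES(sig, names(sig)), "smaller than the universe")
})

test_that("regulonES is the likelihood-weighted signed mean", {
    sig <- c(x = 2, y = -2, z = 0.5)
    r <- Regulon("T", c("x", "y"), mode = c(1, -1), likelihood = c(1, 1))
    expect_equal(regulonES(sig, r, minSize = 2L), 2)
    expect_equal(regulonES(c(x = 0, y = 0, z = 0), r, minSize = 2L), 0)

    set.seed(8)
    sig2 <- randomSignature(40, seed = 8)
    for (i in 1:20) {
        tg <- sample(names(sig2), 8)
        md <- runif(8, -1, 1)
        lk <- runif(8, 0.1, 1)
        r2 <- Regulon("T", tg, md, lk)
        expect_equal(regulonES(sig2, r2, minSize = 8L),
                     sum(lk * md * sig2[tg]) / sum(lk), tolerance = 1e-12)
        # linearity in the signature
        expect_equal(regulonES(3.7 * sig2, r2, minSize = 8L),
                     3.7 * regulonES(sig2, r2, minSize = 8L),
                     tolerance = 1e-12)
    }
    expect_error(regulonES(sig, r, minSize = 10L), "minSize")
})

test_that("permutation nulls are seeded, centred and bounded", {
    sig <- randomSignature(60, seed = 9)
    r <- Regulon("T", names(sig)[1:12])
    n1 <- permutationNull(sig, r, nPerm = 50L, seed = 4L)
    n2 <- permutationNull(sig, r, nPerm = 50L, seed = 4L)
    expect_identical(n1, n2)

    # symmetric signature, singleton-like small set: null mean ~ 0
    symSig <- stats::setNames(c(seq(-1, -0.01, length.out = 50),
                                seq(0.01, 1, length.out = 50)),
                              sprintf("s%03d", 1:100))
    null <- permutationNull(symSig, Regulon("T", names(symSig)[1:10]),
                            nPerm = 2000L, seed = 11L)
    expect_lt(abs(mean(null)), 3 * stats::sd(null) / sqrt(2000))

    small <- permutationNull(sig, r, nPerm = 10L, seed = 1L)
    expect_length(small, 10L)
    expect_gte(nesFromNull(gseaES(sig, names(sig)[1:12]), small)$p, 1 / 11)

    expect_error(permutationNull(sig, r, scheme = "sample_shuffle"),
                 "requires")
    expect_error(permutationNull(sig, r, nPerm = 5L), "at least 10")
})

test_that("sample shuffling recomputes the signature from permuted labels", {
    fx <- normalizedFixture(smallConfig(nGenes = 60L, nTFs = 2L,
                                        targetsPerTF = 10L,
                                        populations = data.frame(
                                            label = c("A", "B"),
                                            n_cells = c(10L, 10L))))
    ln <- assay(fx$sce, "lognorm")
    pop <- colData(fx$sce)$population
    de <- suppressWarnings(wilcoxonDE(ln, which(pop == "A"),
                                      which(pop == "B")))
    sig <- groupSignature(de)
    r <- Regulon("T", names(sig)[1:15])
    null <- permutationNull(sig, r, nPerm = 10L, scheme = "sample_shuffle",
                            seed = 2L, exprs = ln,
                            cellsA = which(pop == "A"),
                            cellsB = which(pop == "B"))
    expect_length(null, 10L)
    expect_true(all(is.finite(null)))
})

test_that("NES definition: degenerate nulls, scaling and monotonicity", {
    np <- nesFromNull(0.4, rep(0.4, 100))
    expect_equal(np$nes, 1)
    expect_equal(np$p, 1)
    nn <- nesFromNull(-0.4, rep(-0.4, 100))
    expect_equal(nn$nes, -1)
    expect_equal(nn$p, 1)

    null <- c(rep(0.2, 50), rep(-0.2, 50))
    expect_equal(nesFromNull(0.4, null)$nes, 2)
    expect_equal(nesFromNull(-0.4, null)$nes, -2)

    grid <- seq(-1, 1, by = 0.1)
    nes <- vapply(grid, function(e) nesFromNull(e, null)$nes, numeric(1L))
    expect_true(all(diff(nes) > 0))

    expect_error(nesFromNull(0.3, rep(0, 10)), "degenerate")
})

test_that("mra is antisymmetric under signature sign flip (shared seed)", {
    truth <- makeTruth(smallConfig(nGenes = 200L, nTFs = 4L,
                                   targetsPerTF = 20L))
    sig <- randomSignature(200, seed = 13)
    names(sig) <- truth@genes$gene_id
    up <- mra(sig, truth@regulons, nPerm = 200L, seed = 17L)
    dn <- mra(-sig, truth@regulons, nPerm = 200L, seed = 17L)
    dn <- dn[match(up$name, dn$name), ]
    expect_equal(dn$nes, -up$nes, tolerance = 1e-12)
    expect_equal(dn$p_value, up$p_value)
    expect_true(all(diff(up$nes) <= 0))   # sorted by NES descending
})

test_that("undersized regulons are skipped with a warning in batch mode", {
    sig <- randomSignature(100, seed = 14)
    rl <- RegulonList(Regulon("BIG", names(sig)[1:20]),
                      Regulon("TINY", names(sig)[1:3]))
    expect_warning(res <- mra(sig, rl, nPerm = 50L, seed = 1L), "TINY")
    expect_identical(res$name, "BIG")
})

test_that("gseaBatch flags extreme sets and keeps the NES ordering", {
    sig <- randomSignature(300, seed = 15)
    topSet <- names(sort(sig, decreasing = TRUE))[1:50]
    set.seed(16)
    sets <- list(TOP = topSet,
                 RAND1 = sample(names(sig), 40),
                 RAND2 = sample(names(sig), 40))
    res <- gseaBatch(sig, sets, nPerm = 200L, seed = 3L)
    expect_true(all(diff(res$nes) <= 0))
    top <- res[res$name == "TOP", ]
    expect_gt(top$nes, 0)
    expect_equal(top$p_value, 1 / 201)
    expect_identical(res$name[1], "TOP")
})

test_that("random gene sets are not called enriched under the null", {
    sig <- randomSignature(250, seed = 18)
    hits <- 0L
    for (s in 1:20) {
        set.seed(s)
        rnd <- sample(names(sig), 30)
        res <- gseaBatch(sig, list(R = rnd), nPerm = 200L, seed = 100L + s)
        if (res$p_value > 0.05) hits <- hits + 1L
    }
    expect_gte(hits, 18L)
})
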