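test_that("gene statistics: constant genes and detection fractions", {
    x <- rbind(matrix(seq_len(48) / 10, 12, 4), const = rep(2, 4))
    rownames(x) <- c(sprintf("g%02d", 1:12), "const")
    counts <- matrix(1L, 13, 4, dimnames = dimnames(x))
    counts[2, 1:2] <- 0L
    st <- suppressWarnings(geneStats(x, counts))  # tiny fixture: loess grumbles
    expect_equal(st$variance[st$gene == "const"], 0)
    expect_equal(st$detection_fraction[st$gene == "const"], 1)
    expect_equal(st$detection_fraction[st$gene == "g02"], 0.5)
    expect_error(geneStats(x[1:5, ], counts[1:5, ]), "loess")
})

test_that("loess de-trending removes an exactly quadratic variance trend", {
    set.seed(9)
    nGenes <- 60L
    nCells <- 40L
    mu <- sort(runif(nGenes, -2, 4))
    v <- 0.1 + 0.05 * mu + 0.02 * mu^2
    # two-point rows realize mean mu exactly and sample variance
    # d^2 * n/(n-1), so pick d to hit v on the nose
    d <- sqrt(v * (nCells - 1) / nCells)
    x <- mu + sweep(matrix(rep(rep(c(-1, 1), each = nCells / 2), nGenes),
                           nGenes, nCells, byrow = TRUE), 1L, d, "*")
    rownames(x) <- sprintf("g%02d", seq_len(nGenes))
    st <- geneStats(x, matrix(1L, nGenes, nCells))
    expect_equal(st$variance, unname(v), tolerance = 1e-10)
    expect_lt(max(abs(st$residual_variance)), 1e-6)
})

test_that("wilcoxonDE matches exact enumeration on 5-vs-5 samples", {
    set.seed(21)
    x <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("c%02d", 1:10)))
    de <- wilcoxonDE(x, 1:5, 6:10)
    pExact <- vapply(seq_len(30), function(g)
        enumWilcoxP(x[g, 1:5], x[g, 6:10]), numeric(1L))
    expect_equal(de$p_value, pExact, tolerance = 5e-4)
})

test_that("wilcoxonDE agrees with stats::wilcox.test on tied data", {
    set.seed(22)
    x <- matrix(rpois(40 * 60, 2), 40, 60,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
    x <- log1p(x)
    de <- suppressWarnings(wilcoxonDE(x, 1:30, 31:60))
    pRef <- vapply(seq_len(40), function(g)
        suppressWarnings(stats::wilcox.test(x[g, 1:30],
                                            x[g, 31:60])$p.value),
        numeric(1L))
    expect_equal(de$p_value, pRef, tolerance = 1e-10)
})

test_that("wilcoxonDE detects overwhelming shifts and is antisymmetric", {
    set.seed(23)
    x <- matrix(rnorm(5 * 200), 5, 200,
                dimnames = list(paste0("g", 1:5), NULL))
    x[1, 1:100] <- x[1, 1:100] + 2
    de <- wilcoxonDE(x, 1:100, 101:200)
    expect_lt(de$p_value[1], 1e-10)
    expect_gt(de$avg_logFC[1], 0)
    rev <- wilcoxonDE(x, 101:200, 1:100)
    expect_equal(rev$p_value, de$p_value)
    expect_equal(rev$avg_logFC, -de$avg_logFC)
    expect_equal(rev$pct_1, de$pct_2)
})

test_that("genes tied across both groups get p = 1 with a warning", {
    x <- rbind(flat = rep(1, 10), ok = c(rnorm(10)))
    expect_warning(de <- wilcoxonDE(x, 1:5, 6:10), "tied")
    expect_equal(de$p_value[de$gene == "flat"], 1)
    expect_equal(nrow(de), 2L)
})

test_that("Benjamini-Hochberg equals the step-up oracle", {
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)),
                 c(0.03, 0.03, 0.03))
    expect_equal(benjaminiHochberg(rep(0.2, 7)), rep(0.2, 7))
    set.seed(31)
    for (i in 1:25) {
        p <- runif(sample(1:12, 1))
        adj <- benjaminiHochberg(p)
        expect_equal(adj, bruteBH(p), tolerance = 1e-12)
        expect_true(all(diff(adj[order(p)]) > -1e-12))
    }
    expect_error(benjaminiHochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("signed-z signatures respect sign, magnitude and the p floor", {
    de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                     p_value = c(1, 0.01, 0.01, 0.5, 0),
                     avg_logFC = c(0.5, 1, -1, 0.3, 2))
    sig <- groupSignature(de)
    expect_equal(unname(sig["a"]), 0)
    expect_equal(unname(sig["b"]), -unname(sig["c"]))
    expect_gt(sig["b"], sig["d"])       # smaller p, larger score
    expect_true(is.finite(sig["e"]))    # p floored at 1e-300
    expect_equal(unname(sig["e"]),
                 stats::qnorm(1e-300 / 2, lower.tail = FALSE))
})
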