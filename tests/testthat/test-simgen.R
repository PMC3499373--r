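test_that("site-frequency draws are seeded, bounded and reciprocal-shaped", {
    cfg <- sfsConfig(5000, mafMin = 1e-4, mafMax = 0.5, seed = 7)
    f1 <- drawSiteFrequencies(cfg)
    f2 <- drawSiteFrequencies(cfg)
    expect_identical(f1, f2)
    expect_true(all(f1 >= 1e-4 & f1 <= 0.5))

    # closed-form check: under density ~ 1/x on [1e-3, 0.5],
    # P(MAF < 0.01) = ln(0.01/0.001) / ln(0.5/0.001)
    cfg2 <- sfsConfig(1e5, mafMin = 1e-3, mafMax = 0.5, seed = 11)
    f <- drawSiteFrequencies(cfg2)
    pExp <- log(0.01 / 0.001) / log(0.5 / 0.001)
    se <- sqrt(pExp * (1 - pExp) / 1e5)
    expect_lt(abs(mean(f < 0.01) - pExp), 3 * se)

    # Kolmogorov-Smirnov on the probability-integral transform
    u <- log(f / 1e-3) / log(0.5 / 1e-3)
    expect_gt(suppressWarnings(stats::ks.test(u, "punif")$p.value), 0.01)
})

test_that("degenerate SFS configurations are rejected", {
    expect_error(sfsConfig(0), "positive integer")
    expect_error(sfsConfig(10, mafMin = 0.2, mafMax = 0.1), "mafMin")
    expect_error(sfsConfig(10, mafMin = 0.1, mafMax = 0.6), "mafMin")
    expect_error(sfsConfig(10, spectrum = "custom"), "mafGrid")
})

test_that("selection coefficients favor rare sites and are reproducible", {
    expect_identical(assignSelectionCoeffs(numeric(0)), numeric(0))
    s1 <- assignSelectionCoeffs(c(1e-4, 0.4), seed = 3)
    expect_identical(s1, assignSelectionCoeffs(c(1e-4, 0.4), seed = 3))
    expect_true(all(s1 >= 0))

    mafs <- rep(c(2e-4, 5e-3), each = 10000)
    s <- assignSelectionCoeffs(mafs, seed = 5)
    pRare <- mean(s[mafs == 2e-4] > 1e-4)
    pLessRare <- mean(s[mafs == 5e-3] > 1e-4)
    expect_gt(pRare, pLessRare)
    expect_error(assignSelectionCoeffs(c(0.2, 0.7)), "0, 0.5")
})

test_that("genotype sampling follows Hardy-Weinberg binomials", {
    G <- sampleGenotypes(0.25, 50000, seed = 9)
    expect_identical(genotypeCounts(sampleGenotypes(0.25, 50000, seed = 9)),
                     genotypeCounts(G))
    cm <- mean(genotypeCounts(G))
    expect_lt(abs(cm - 0.5), 3 * sqrt(2 * 0.25 * 0.75 / 50000))

    # genotype-class frequencies vs HWE proportions
    tab <- tabulate(genotypeCounts(G) + 1L, 3L)
    expect_gt(stats::chisq.test(
        tab, p = c(0.75^2, 2 * 0.25 * 0.75, 0.25^2))$p.value, 1e-3)

    g1 <- genotypeCounts(sampleGenotypes(0.3, 1, seed = 1))
    expect_true(g1 %in% 0:2)
    expect_error(sampleGenotypes(0.7, 10), "0, 0.5")
    expect_error(sampleGenotypes(0.1, 0), "positive integer")
})

test_that("GenotypeMatrix enforces its invariants", {
    expect_error(toyGenotypes(matrix(3L, 2, 1)), "0, 1, 2")
    expect_error(toyGenotypes(matrix(0:1, 2, 1), maf = 0.7), "maf")
    G <- toyGenotypes(rbind(c(0, 1), c(2, 0)))
    expect_equal(nIndividuals(G), 2)
    expect_equal(nSites(G), 2)
    expect_equal(empiricalMaf(G), c(s1 = 0.5, s2 = 0.25))
    expect_equal(dim(genotypeCounts(G[1, ])), c(1L, 2L))
})
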