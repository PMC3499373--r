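# Codings and statistics on fully controlled toy data, with brute-force
# oracles for VT, SKAT and KBAC.

test_that("CMC carrier indicator respects the MAF threshold", {
    # sites 1-2 rare, site 3 common (MAF 0.25 here)
    cnt <- rbind(c(0, 2, 0), c(0, 0, 1), c(1, 0, 1), c(0, 0, 0))
    G <- toyGenotypes(cnt, maf = c(0.005, 0.008, 0.02))
    cd <- codeCMC(G, 0.01)
    expect_equal(cd@x, c(1, 0, 1, 0))
    expect_equal(cd@sites, 1:2)

    # threshold excludes the MAF 0.02 site entirely
    expect_false(3L %in% codeCMC(G, 0.01)@sites)
    expect_error(codeCMC(G, 0.001), "no polymorphic sites")
})

test_that("WSS weights follow the pseudo-count formula", {
    # n = 4, one minor allele at site 1: q = 2/10, w = 1/sqrt(4*0.16)
    cnt <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0))
    G <- toyGenotypes(cnt, maf = c(0.005, 0.005))
    cd <- codeWSS(G, 0.01)
    expect_equal(cd@weights[1], 1.25)
    # monomorphic site: finite weight, zero contribution
    expect_true(is.finite(cd@weights[2]))
    expect_equal(cd@x, c(1.25, 0, 0, 0))

    # linearity at fixed weights
    G2 <- toyGenotypes(2L * cnt, maf = c(0.005, 0.005))
    expect_equal(as.vector(genotypeCounts(G2) %*% cd@weights), 2 * cd@x)
})

test_that("burden score is the centered cross-product", {
    expect_equal(burdenScore(c(1, -1, 0), c(1, 0, 1)), 1)
    expect_equal(burdenScore(rep(0, 5), c(1, 0, 1, 0, 1)), 0)
    expect_warning(u <- burdenScore(rnorm(5), rep(2, 5)), "constant")
    expect_equal(u, 0)

    set.seed(1)
    e <- rnorm(30); x <- rbinom(30, 2, 0.2)
    p <- sample(30)
    expect_equal(burdenScore(e[p], x[p]), burdenScore(e, x))
    # location invariance after centering the coding
    expect_equal(burdenScore(e + 5, x), burdenScore(e, x))
})

test_that("single-variant score matches burden on one site and flips sign", {
    set.seed(2)
    e <- rnorm(20); g <- rbinom(20, 2, 0.3)
    expect_equal(singleVariantScore(e, g), burdenScore(e, g))
    expect_equal(singleVariantScore(e, 2 - g), -singleVariantScore(e, g))
    expect_error(singleVariantScore(e, rep(0, 20)), "monomorphic")
})

test_that("VT maximizes the standardized score over observed thresholds", {
    set.seed(3)
    G <- randomRareGenotypes(20, 3, maf = 0.2, seed = 3)
    # force MAFs under the cap
    G@sites$maf <- empiricalMaf(G)
    e <- rnorm(20)
    got <- vtStatistic(e, G, mafCap = 0.5)

    # brute force: enumerate thresholds, recompute everything
    f <- empiricalMaf(G)
    thr <- sort(unique(f[f > 0 & f <= 0.5]))
    zBrute <- vapply(thr, function(t) {
        x <- rowSums(genotypeCounts(G)[, f > 0 & f <= t, drop = FALSE])
        u <- sum((e - mean(e)) * x)
        v <- sum((e - mean(e))^2) * sum((x - mean(x))^2) / (length(e) - 1)
        u / sqrt(v)
    }, numeric(1))
    expect_equal(got$statistic, max(abs(zBrute)), tolerance = 1e-12)
    expect_equal(got$threshold, thr[which.max(abs(zBrute))])
    expect_true(all(got$statistic >= abs(got$z$z)))

    # single distinct MAF: reduces to the plain standardized burden
    G1 <- toyGenotypes(cbind(c(1L, 0L, 0L, 1L)), maf = 0.25)
    e4 <- c(2, -1, 0, 1)
    v1 <- vtStatistic(e4, G1, mafCap = 0.5)
    x <- c(1, 0, 0, 1)
    u <- sum((e4 - mean(e4)) * x)
    vv <- sum((e4 - mean(e4))^2) * sum((x - mean(x))^2) / 3
    expect_equal(v1$statistic, abs(u / sqrt(vv)))

    # cap below the smallest observed MAF errors out
    expect_error(vtStatistic(e, G, mafCap = 1e-4), "no polymorphic")
})

test_that("SKAT fast form equals the kernel double sum", {
    expect_equal(skatStatistic(c(1, -1), toyGenotypes(cbind(c(1L, 0L)),
                                                      maf = 0.25),
                               weights = "none", mafThreshold = 0.5), 1)

    G <- randomRareGenotypes(10, 4, maf = 0.15, seed = 5)
    j <- codeCount(G, 0.5)@sites         # polymorphic sites
    set.seed(6)
    e <- rnorm(10)
    w <- runif(length(j), 0.5, 2)
    qFast <- skatStatistic(e, G, weights = w, mafThreshold = 0.5)
    cnt <- genotypeCounts(G)[, j, drop = FALSE]
    K <- cnt %*% diag(w) %*% t(cnt)
    qSlow <- sum(outer(e, e) * K)
    expect_equal(qFast, qSlow, tolerance = 1e-12)

    # residuals orthogonal to every genotype column give Q = 0
    eOrth <- stats::residuals(stats::lm(rnorm(10) ~ cnt))
    expect_lt(skatStatistic(eOrth, G, weights = w, mafThreshold = 0.5),
              1e-20 * qFast + 1e-12)
})

test_that("KBAC groups genotype patterns and weights by enrichment", {
    # two carrier groups with zero mean residual: all weights 0.5, T = 0
    cnt <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 0), c(0, 0))
    G <- toyGenotypes(cnt, maf = c(0.005, 0.005))
    e0 <- c(1, -1, 2, -2, 3, -3)
    expect_equal(kbacStatistic(e0, G, 0.01), 0)

    # saturation: one strongly positive carrier group
    eBig <- c(10, 10, 0.1, -0.1, -5, -5)
    grpMeans <- c(10, 0)
    tGot <- kbacStatistic(eBig, G, 0.01)
    # group {1,2}: w ~ 1, contribution ~ 2 * 10; group {3,4}: w = 0.5, 0
    expect_lt(abs(tGot - 20), 0.5)

    # brute-force oracle on 12 individuals
    G12 <- randomRareGenotypes(12, 3, maf = 0.25, seed = 8)
    G12@sites$maf <- pmax(empiricalMaf(G12), 1e-6)
    set.seed(9)
    e <- rnorm(12)
    tPkg <- kbacStatistic(e, G12, mafThreshold = 0.5)
    cnt12 <- genotypeCounts(G12)[, empiricalMaf(G12) > 0, drop = FALSE]
    key <- apply(cnt12, 1, paste, collapse = "-")
    sigma <- sd(e)
    tOracle <- 0
    for (k in setdiff(unique(key), paste(rep(0, ncol(cnt12)),
                                         collapse = "-"))) {
        idx <- which(key == k)
        ek <- mean(e[idx])
        tOracle <- tOracle +
            pnorm(ek * sqrt(length(idx)) / sigma) * length(idx) * ek
    }
    expect_equal(tPkg, tOracle, tolerance = 1e-12)

    # degenerate: everyone shares one pattern, so no site carries
    # information and the grouping refuses
    G0 <- toyGenotypes(matrix(0L, 4, 1), maf = 0.01)
    expect_error(kbacStatistic(rnorm(4), G0, 0.5), "no polymorphic")
})
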