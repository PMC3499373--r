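test_that("permutation p-values follow the add-one convention", {
    # sorted residuals against a sorted coding: the observed score is
    # the rearrangement maximum, so all 19 permutations fall below it
    e <- sort(rnorm(12))
    G <- toyGenotypes(cbind(sort(rbinom(12, 2, 0.4))), maf = 0.4)
    res <- permutationPvalue(function(e, G)
        burdenScore(e, codeCount(G, 0.5)), e, G, B = 19, seed = 1,
        sided = "one-sided-upper")
    expect_s4_class(res, "TestResult")
    expect_equal(pValue(res), 1 / 20)

    # constant statistic: p = 1
    resC <- permutationPvalue(function(e, G) 1, e, G, B = 50, seed = 2)
    expect_equal(pValue(resC), 1)

    expect_error(permutationPvalue(function(e, G) 1, e, G, B = 0),
                 "positive integer")
})

test_that("vectorized batch engine agrees with observed statistics and is
           reproducible", {
    G <- randomRareGenotypes(80, 6, maf = 0.03, seed = 21)
    set.seed(22)
    e <- rnorm(80)
    r1 <- regionTests(e, G, B = 200, seed = 7, mafThreshold = 0.5,
                      vtCap = 0.5)
    r2 <- regionTests(e, G, B = 200, seed = 7, mafThreshold = 0.5,
                      vtCap = 0.5)
    expect_identical(r1, r2)

    expect_equal(r1$statistic[r1$test == "cmc"],
                 burdenScore(e, codeCMC(G, 0.5)))
    expect_equal(r1$statistic[r1$test == "wss"],
                 burdenScore(e, codeWSS(G, 0.5)))
    expect_equal(r1$statistic[r1$test == "vt"],
                 vtStatistic(e, G, 0.5)$statistic)
    expect_equal(r1$statistic[r1$test == "skat"],
                 skatStatistic(e, G, mafThreshold = 0.5))
    expect_equal(r1$statistic[r1$test == "kbac"],
                 kbacStatistic(e, G, mafThreshold = 0.5))
    expect_true(all(r1$p_empirical > 0 & r1$p_empirical <= 1))

    # the batch engine matches the generic per-permutation engine
    # (same seed => same permutation stream)
    gen <- permutationPvalue(function(e, G)
        skatStatistic(e, G, mafThreshold = 0.5), e, G, B = 200, seed = 7,
        sided = "one-sided-upper")
    expect_equal(r1$p_empirical[r1$test == "skat"], pValue(gen))
})

test_that("analytic SKAT tail matches chi-square in one dimension and
           permutation in several", {
    # single site: p equals the chi2(1) tail of the standardized score
    g <- c(2, 0, 1, 0, 0, 1, 0, 0)
    G1 <- toyGenotypes(cbind(g), maf = 0.25)
    set.seed(31)
    e <- rnorm(8)
    q <- skatStatistic(e, G1, weights = 1, mafThreshold = 0.5)
    lam <- stats::var(e) * sum((g - mean(g))^2)
    expect_equal(skatAnalyticP(q, e, G1, weights = 1, mafThreshold = 0.5),
                 stats::pchisq(q / lam, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
    expect_equal(skatAnalyticP(0, e, G1, weights = 1, mafThreshold = 0.5),
                 1)

    # several sites: the Imhof inversion matches a Monte-Carlo draw
    # from the matching Gaussian null (same eigenstructure)
    G <- randomRareGenotypes(300, 5, maf = 0.04, seed = 32)
    set.seed(33)
    e <- rnorm(300)
    w <- madsenBrowningWeights(G, 1:5)
    q <- skatStatistic(e, G, mafThreshold = 0.5)
    pA <- skatAnalyticP(q, e, G, mafThreshold = 0.5)
    B <- 4e4
    Z <- matrix(rnorm(300 * B, sd = stats::sd(e)), 300, B)
    Z <- sweep(Z, 2L, colMeans(Z))       # centered, like OLS residuals
    qMc <- as.vector(crossprod(Z, genotypeCounts(G))^2 %*% w)
    pMc <- mean(qMc >= q)
    expect_lt(abs(pA - pMc), 3 * sqrt(pMc * (1 - pMc) / B))

    # against the permutation null the analytic tail is approximate
    # (finite-sample moment mismatch), but close
    res <- regionTests(e, G, tests = "skat", B = 2e4, seed = 34,
                       mafThreshold = 0.5, analytic = TRUE)
    expect_lt(abs(res$p_analytic - res$p_empirical), 0.04)
})

test_that("normal approximation to the burden permutation null is
           accurate", {
    expect_equal(burdenAnalyticP(0, rnorm(30), rbinom(30, 2, 0.3)), 1)
    expect_warning(p <- burdenAnalyticP(1, rnorm(30), rep(1, 30)),
                   "zero permutation variance")
    expect_equal(p, 1)

    G <- randomRareGenotypes(500, 8, maf = 0.03, seed = 41)
    set.seed(42)
    e <- rnorm(500)
    res <- regionTests(e, G, tests = "wss", B = 1e5, seed = 43,
                       mafThreshold = 0.5, analytic = TRUE)
    seMc <- sqrt(res$p_empirical * (1 - res$p_empirical) / 1e5)
    expect_lt(abs(res$p_analytic - res$p_empirical), 3 * seMc + 0.002)

    # two-sided p is invariant to negating the residuals
    x <- codeWSS(G, 0.5)
    u <- burdenScore(e, x)
    expect_equal(burdenAnalyticP(u, e, x), burdenAnalyticP(-u, -e, x))
})

test_that("null permutation p-values are uniform or super-uniform", {
    G <- randomRareGenotypes(40, 5, maf = 0.05, seed = 51)
    set.seed(52)
    reps <- 400
    p <- vapply(seq_len(reps), function(r) {
        e <- rnorm(40)
        regionTests(e, G, tests = "wss", B = 99,
                    mafThreshold = 0.5)$p_empirical
    }, numeric(1))
    upper <- stats::qbinom(0.995, reps, 0.05) / reps
    expect_lte(mean(p <= 0.05), upper)
})

test_that("monotonicity: larger observed statistics never raise p", {
    draws <- c(0.2, 0.5, 0.9, 1.4)
    p <- vapply(c(0.1, 0.6, 1.0, 2.0), function(t)
        extremeRV:::permPFromDraws(t, draws, "one-sided-upper"),
        numeric(1))
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0))
})
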