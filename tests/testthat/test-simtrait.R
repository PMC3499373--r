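eligibleFixture <- function(nEligible = 100, nNeutral = 20) {
    m <- nEligible + nNeutral
    toyGenotypes(matrix(0L, 2, m),
                 maf = rep(1e-3, m),
                 selCoeff = c(rep(1e-3, nEligible), rep(1e-5, nNeutral)))
}

test_that("causal sets are drawn independently from the eligible pool", {
    G <- eligibleFixture()
    G1 <- selectCausalSets(G, 0.5, seed = 1)
    sites <- siteInfo(G1)
    expect_equal(sum(sites$causal_primary), 50)
    expect_equal(sum(sites$causal_secondary), 50)
    expect_true(all(which(sites$causal_primary) <= 100))

    # independent draws: overlap is hypergeometric, mean 25
    ov <- vapply(1:10000, function(s) {
        si <- siteInfo(selectCausalSets(G, 0.5, seed = s))
        sum(si$causal_primary & si$causal_secondary)
    }, numeric(1))
    vHyp <- 50 * 0.5 * 0.5 * 50 / 99
    expect_lt(abs(mean(ov) - 25), 3 * sqrt(vHyp / 10000))

    all1 <- selectCausalSets(G, 1, seed = 2)
    expect_true(all(siteInfo(all1)$causal_primary[1:100]))
    expect_true(all(siteInfo(all1)$causal_secondary[1:100]))

    GNone <- eligibleFixture(nEligible = 0, nNeutral = 5)
    expect_error(selectCausalSets(GNone, 0.5), "sel_coeff > 1e-4")
})

test_that("effect sizes follow the magnitude model and sign fractions", {
    G <- eligibleFixture(10, 0)
    G@sites$maf <- c(rep(0.1, 5), rep(0.001, 5))
    G <- selectCausalSets(G, 1, seed = 1)

    bFixed <- effectSizes(G, "primary", model = "fixed", c1 = 0.25)
    expect_true(all(bFixed == 0.25))

    b82 <- effectSizes(G, "secondary", c1 = 0.5, fracPositive = 0.8,
                       seed = 4)
    expect_equal(sum(b82 > 0), 8)
    expect_equal(sum(b82 < 0), 2)

    bLog <- effectSizes(G, "primary", model = "log-maf", c1 = 0, c2 = 1)
    expect_equal(unique(abs(bLog[1:5])) / unique(abs(bLog[6:10])), 1 / 3)

    # non-causal sites get exactly zero
    G0 <- eligibleFixture(10, 10)
    G0 <- selectCausalSets(G0, 0.5, seed = 2)
    b <- effectSizes(G0, "primary", c1 = 0.3)
    expect_true(all(b[!siteInfo(G0)$causal_primary] == 0))
    expect_true(all(b[siteInfo(G0)$causal_primary] != 0))
})

test_that("trait simulation reproduces the bivariate residual model", {
    n <- 1e5
    G <- sampleGenotypes(c(0.1, 0.2), n, seed = 3)
    ph <- simulateTraits(G, rho = 0.6, seed = 5)
    seZ <- 3 * (1 - 0.6^2) / sqrt(n)
    expect_lt(abs(stats::cor(ph$y1, ph$y2) - 0.6), seZ)

    ph0 <- simulateTraits(G, rho = 0, seed = 6)
    expect_lt(abs(stats::cor(ph0$y1, ph0$y2)), 3 / sqrt(n))

    # OLS consistency for a single causal site
    n2 <- 2e5
    G1 <- sampleGenotypes(0.1, n2, seed = 7)
    ph1 <- simulateTraits(G1, betaPrimary = 0.5, seed = 8)
    g <- as.vector(genotypeCounts(G1))
    slope <- stats::coef(stats::lm(ph1$y1 ~ g))[2]
    expect_lt(abs(slope - 0.5), 3 / sqrt(n2 * 2 * 0.1 * 0.9))

    # variance decomposition with independent sites
    ph2 <- simulateTraits(G, betaPrimary = c(0.5, -0.3), seed = 9)
    varExp <- 1 + 0.5^2 * 2 * 0.1 * 0.9 + 0.3^2 * 2 * 0.2 * 0.8
    expect_lt(abs(stats::var(ph2$y1) - varExp), 0.03)

    expect_error(simulateTraits(G, betaPrimary = 1), "one entry per site")
    expect_error(simulateTraits(G, rho = 2), "rho")
})

test_that("medication adjustment shifts only treated individuals", {
    sys <- c(130, 120, 145)
    med <- c(TRUE, FALSE, TRUE)
    expect_equal(adjustMedication(sys, med, 10), c(140, 120, 155))
    expect_equal(adjustMedication(sys, rep(FALSE, 3), 10), sys)
    expect_equal(adjustMedication(80, TRUE, 5), 85)
    expect_error(adjustMedication(sys, med[1:2], 10), "lengths differ")
})

test_that("covariate-adjusted quantile normalization yields normal scores", {
    set.seed(10)
    x <- rnorm(200)
    covs <- cbind(age = rnorm(200), sex = rbinom(200, 1, 0.5))
    z <- covariateAdjustQuantileNormalize(x + covs %*% c(1, -2), covs)
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(stats::var(z) - 1), 0.05)

    # n = 3 distinct residuals map to Phi^{-1}((2r-1)/6) in rank order
    z3 <- covariateAdjustQuantileNormalize(c(5, -2, 1))
    expect_equal(z3, stats::qnorm(c(5, 1, 3) / 6))

    expect_error(
        covariateAdjustQuantileNormalize(rnorm(10), cbind(rep(1, 10))),
        "rank deficient")
})
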