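test_that("without truncation the MLE reduces to ordinary least squares", {
    set.seed(11)
    n <- 400
    x <- rbinom(n, 2, 0.1)
    X1 <- cbind(age = rnorm(n))
    y <- 1 + 0.5 * X1[, 1] + 0.4 * x + rnorm(n, sd = 0.8)
    f <- fitTruncatedPrimary(y, X1 = X1, coding = x, region = NULL)
    ols <- stats::lm(y ~ X1 + x)
    expect_equal(c(f$gamma1, f$betaP), unname(stats::coef(ols)),
                 tolerance = 1e-6)
    expect_equal(f$sigma1,
                 sqrt(mean(stats::residuals(ols)^2)), tolerance = 1e-6)
    expect_true(f$converged)
})

test_that("degenerate codings are dropped, boundary fits error", {
    set.seed(12)
    y <- rnorm(100)
    expect_message(f <- fitTruncatedPrimary(y, coding = rep(0, 100)),
                   "non-identifiable")
    expect_true(is.na(f$betaP))
    # selected values outside the declared region are rejected
    r <- SelectionRegion(-2, 2)
    expect_error(fitTruncatedPrimary(rep(0.5, 50), region = r),
                 "outside the selection region")
})

test_that("conditional secondary fit recovers tau and centers residuals", {
    set.seed(13)
    n <- 2000
    y1 <- rnorm(n)
    y2 <- 0.6 * y1 + rnorm(n, sd = 0.8)
    f <- fitConditionalSecondary(y2, y1 = y1, mu1Hat = rep(0, n))
    expect_lt(abs(f$tau - 0.6), 3 * 0.8 / sqrt(n))
    expect_lt(abs(mean(f$residuals)), 1e-12)

    # collinearity is reported with the offending column
    expect_error(
        fitConditionalSecondary(y2, X2 = cbind(dup = y1), y1 = y1,
                                mu1Hat = rep(0, n)),
        "collinear")
})

test_that("truncated fit recovers parameters under extreme sampling", {
    # correct specification: the primary effect acts through the coding
    reps <- 25
    est <- t(vapply(seq_len(reps), function(r) {
        withr::with_seed(100 + r, {
            n <- 40000
            x <- rbinom(n, 2, 0.005)
            y1 <- 0.5 * x + rnorm(n)
            ph2 <- 0.6 * (y1 - 0.5 * x) + sqrt(1 - 0.36) * rnorm(n)
            asc <- selectExtremes(y1, 2000)
            i <- asc@indices
            f1 <- fitTruncatedPrimary(y1[i], coding = x[i],
                                      region = asc@region)
            f2 <- fitConditionalSecondary(ph2[i], y1 = y1[i],
                                          mu1Hat = f1$mu1)
            c(betaP = f1$betaP, sigma1 = f1$sigma1, tau = f2$tau)
        })
    }, numeric(3)))
    # naive OLS on the selected sample is badly attenuated/inflated;
    # the truncated MLE is not
    expect_lt(abs(mean(est[, "betaP"]) - 0.5),
              3 * stats::sd(est[, "betaP"]) / sqrt(reps))
    expect_lt(abs(mean(est[, "sigma1"]) - 1),
              3 * stats::sd(est[, "sigma1"]) / sqrt(reps))
    expect_lt(abs(mean(est[, "tau"]) - 0.6),
              3 * stats::sd(est[, "tau"]) / sqrt(reps))
})

test_that("residuals match the plain conditional fit when the gene has no
           primary effect coding", {
    set.seed(15)
    n <- 3000
    y1 <- rnorm(n)
    y2 <- 0.4 * y1 + rnorm(n)
    asc <- selectExtremes(y1, 400)
    i <- asc@indices
    fit <- computeResiduals(y1[i], y2[i], region = asc@region)
    ref <- stats::residuals(stats::lm(y2[i] ~ y1[i]))
    expect_equal(residuals(fit), unname(ref), tolerance = 1e-10)
})

test_that("corrected residuals decorrelate from the coding where naive ones
           do not", {
    # the primary-trait effect acts through the rare-allele count, so
    # the scalar nuisance model is correctly specified
    reps <- 20
    cors <- t(vapply(seq_len(reps), function(r) {
        withr::with_seed(200 + r, {
            n <- 50000
            G <- simulateRegion(sfsConfig(150), n)
            x <- codeCount(G, 0.01)@x
            e1 <- rnorm(n)
            y1 <- 0.5 * x + e1
            y2 <- 0.6 * e1 + sqrt(1 - 0.36) * rnorm(n)
            asc <- selectExtremes(y1, 2500)
            i <- asc@indices
            fit <- computeResiduals(y1[i], y2[i],
                                    primaryCoding = x[i],
                                    region = asc@region)
            eNaive <- y2[i] - mean(y2[i])
            c(corrected = stats::cor(residuals(fit), x[i]),
              naive = stats::cor(eNaive, x[i]))
        })
    }, numeric(2)))
    expect_lt(abs(mean(cors[, "corrected"])),
              3 * stats::sd(cors[, "corrected"]) / sqrt(reps))
    # ignoring the ascertainment and the primary trait leaves a
    # systematic residual correlation with the genotype coding
    expect_gt(abs(mean(cors[, "naive"])),
              4 * stats::sd(cors[, "naive"]) / sqrt(reps))
})

test_that("naive-analysis bias vanishes only without selection pressure
           on the coding", {
    expect_equal(naiveBias(0.5, 0, 0.025, 0.975, 0.02), 0)
    expect_equal(naiveBias(0, 0.6, 0.025, 0.975, 0.02), 0)

    b <- naiveBias(0.5, 0.6, 0.025, 0.975, 0.02)
    expect_gt(abs(b), 0)
    # odd in rho
    expect_equal(naiveBias(0.5, -0.6, 0.025, 0.975, 0.02), -b)

    # approximately linear in betaP for |betaP| <= 0.5
    bp <- seq(-0.5, 0.5, length.out = 11)
    bias <- vapply(bp, function(p) naiveBias(p, 0.6, 0.05, 0.95, 0.02),
                   numeric(1))
    secant <- bias[11] / 0.5 * bp
    expect_lt(max(abs(bias - secant)), 0.1 * max(abs(bias)))

    # the two standard adjustments do not remove the bias
    expect_gt(abs(naiveBias(0.5, 0.6, 0.025, 0.975, 0.02,
                            adjustment = "tail_indicator")), 0)
    expect_gt(abs(naiveBias(0.5, 0.6, 0.025, 0.975, 0.02,
                            adjustment = "tail_meta")), 0)
})
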