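# Permutation engine over exchangeable residuals, plus analytic
# approximations. Permutations shuffle the residuals only; the add-one
# convention p = (1 + #{|T_b| >= |T_obs|}) / (B + 1) guarantees valid,
# never-zero p-values.

#' Permutation p-value for an arbitrary statistic
#'
#' Generic (non-vectorized) engine: \code{statisticFn(e, G)} must be a
#' pure function of the residuals and genotypes. Burden-type statistics
#' are compared two-sided (absolute values); statistics that are already
#' non-negative maxima or quadratic forms use the upper tail.
#'
#' @param statisticFn function of \code{(e, G)} returning a scalar.
#' @param e residual vector (or a \code{\linkS4class{NullFit}}).
#' @param G a \code{\linkS4class{GenotypeMatrix}} (passed through to
#'   \code{statisticFn}).
#' @param B number of permutations (>= 1).
#' @param seed integer seed or \code{NULL}.
#' @param sided \code{"two-sided"} or \code{"one-sided-upper"}.
#' @param test label stored in the result.
#' @return a \code{\linkS4class{TestResult}}.
#' @export
permutationPvalue <- function(statisticFn, e, G, B = 1000, seed = NULL,
                              sided = c("two-sided", "one-sided-upper"),
                              test = "custom") {
    sided <- match.arg(sided)
    if (is(e, "NullFit")) e <- residuals(e)
    if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B))
        stop("'B' must be a positive integer")
    tObs <- statisticFn(e, G)
    n <- length(e)
    tPerm <- withSeed(seed, vapply(seq_len(B), function(b)
        statisticFn(e[sample.int(n)], G), numeric(1)))
    p <- permPFromDraws(tObs, tPerm, sided)
    new("TestResult", test = test, statistic = tObs, pEmpirical = p,
        pAnalytic = NA_real_, nPerm = as.integer(B),
        vtThreshold = NA_real_)
}

permPFromDraws <- function(tObs, tPerm, sided) {
    if (sided == "two-sided") {
        tObs <- abs(tObs)
        tPerm <- abs(tPerm)
    }
    (1 + sum(tPerm >= tObs)) / (length(tPerm) + 1)
}

#' Run region tests with vectorized permutation inference
#'
#' The workhorse: computes any subset of the five region statistics on
#' one residual vector and evaluates their empirical significance on a
#' shared set of residual permutations. Linear codings (CMC, WSS, VT
#' thresholds, SKAT terms) reuse one residual-by-genotype cross-product
#' per permutation batch; KBAC recomputes its adaptive weights inside
#' every permutation from pre-computed genotype groups.
#'
#' @param e residual vector (or a \code{\linkS4class{NullFit}}).
#' @param G \code{\linkS4class{GenotypeMatrix}} of the same individuals.
#' @param tests subset of \code{c("cmc", "wss", "kbac", "vt", "skat")}.
#' @param B number of permutations.
#' @param seed integer seed or \code{NULL}.
#' @param mafThreshold fixed-threshold tests' MAF cutoff (default 1\%).
#' @param vtCap VT's largest candidate threshold (default 5\%).
#' @param skatWeights weight scheme for SKAT (see
#'   \code{\link{skatStatistic}}).
#' @param analytic also compute analytic p-values where available
#'   (normal approximation for burden tests, mixture-of-chi-squares for
#'   SKAT).
#' @param perm optional pre-drawn permutation index matrix
#'   (individuals x B), allowing several residual vectors to share one
#'   permutation batch; overrides \code{B} and \code{seed}.
#' @return \code{data.frame} with one row per test: \code{test},
#'   \code{statistic}, \code{p_empirical}, \code{p_analytic},
#'   \code{n_perm}, \code{vt_threshold}.
#' @export
regionTests <- function(e, G, tests = c("cmc", "wss", "kbac", "vt", "skat"),
                        B = 1000, seed = NULL, mafThreshold = 0.01,
                        vtCap = 0.05, skatWeights = "madsen-browning",
                        analytic = FALSE, perm = NULL) {
    tests <- match.arg(tests, c("cmc", "wss", "kbac", "vt", "skat"),
                       several.ok = TRUE)
    if (is(e, "NullFit")) e <- residuals(e)
    n <- length(e)
    if (n != nIndividuals(G))
        stop("residuals and genotypes cover different individuals")
    if (is.null(perm)) {
        if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B))
            stop("'B' must be a positive integer")
        perm <- withSeed(seed, vapply(seq_len(B), function(b)
            sample.int(n), integer(n)))
    } else {
        if (nrow(perm) != n) stop("'perm' rows must match individuals")
        B <- ncol(perm)
    }
    E <- matrix(e[perm], n, B)
    s0 <- sum(e)
    # one shared residual-permutation x genotype cross-product feeds
    # both the per-threshold (VT) and per-site (SKAT) statistics
    jVt <- if ("vt" %in% tests) qualifyingSites(G, vtCap) else integer()
    jSk <- if ("skat" %in% tests) qualifyingSites(G, mafThreshold)
           else integer()
    jU <- sort(unique(c(jVt, jSk)))
    CU <- if (length(jU))
        crossprod(E, genotypeCounts(G)[, jU, drop = FALSE])
        else NULL
    out <- lapply(tests, function(tst) {
        switch(tst,
            cmc = , wss = {
                coding <- if (tst == "cmc") codeCMC(G, mafThreshold)
                          else codeWSS(G, mafThreshold)
                x <- coding@x
                uObs <- sum(e * (x - mean(x)))
                uPerm <- as.vector(crossprod(E, x)) - mean(x) * s0
                pA <- if (analytic) burdenAnalyticP(uObs, e, coding)
                      else NA_real_
                data.frame(test = tst, statistic = uObs,
                           p_empirical = permPFromDraws(uObs, uPerm,
                                                        "two-sided"),
                           p_analytic = pA, n_perm = B,
                           vt_threshold = NA_real_)
            },
            vt = {
                obs <- vtStatistic(e, G, vtCap)
                f <- siteInfo(G)$maf[jVt]
                ord <- order(f)
                cnt <- genotypeCounts(G)[, jVt[ord], drop = FALSE]
                keep <- !duplicated(f[ord], fromLast = TRUE)
                mj <- ncol(cnt)
                Ltri <- matrix(0, mj, mj)
                Ltri[upper.tri(Ltri, diag = TRUE)] <- 1
                X <- (cnt %*% Ltri)[, keep, drop = FALSE]  # cumulative codings
                xBar <- colMeans(X)
                Sx <- colSums(X^2) - n * xBar^2
                sdU <- sqrt(sum((e - mean(e))^2) * Sx / (n - 1))
                # permuted scores at every threshold from the shared
                # cross-product: cumulate over sorted sites
                Cvt <- CU[, match(jVt[ord], jU), drop = FALSE]
                Up <- sweep((Cvt %*% Ltri)[, keep, drop = FALSE],
                            2L, xBar * s0)                   # B x thresholds
                tPerm <- apply(abs(sweep(Up, 2L, sdU, "/")), 1L, max)
                data.frame(test = "vt", statistic = obs$statistic,
                           p_empirical = permPFromDraws(obs$statistic, tPerm,
                                                        "one-sided-upper"),
                           p_analytic = NA_real_, n_perm = B,
                           vt_threshold = obs$threshold)
            },
            skat = {
                if (!length(jSk))
                    stop(sprintf("no polymorphic sites with MAF <= %g",
                                 mafThreshold))
                j <- jSk
                w <- resolveSkatWeights(G, j, skatWeights)
                cnt <- genotypeCounts(G)[, j, drop = FALSE]
                qObs <- sum(w * as.vector(crossprod(e, cnt))^2)
                Cp <- CU[, match(jSk, jU), drop = FALSE]     # B x m
                qPerm <- as.vector(Cp^2 %*% w)
                pA <- if (analytic)
                    skatAnalyticP(qObs, e, G, weights = skatWeights,
                                  mafThreshold = mafThreshold)
                    else NA_real_
                data.frame(test = "skat", statistic = qObs,
                           p_empirical = permPFromDraws(qObs, qPerm,
                                                        "one-sided-upper"),
                           p_analytic = pA, n_perm = B,
                           vt_threshold = NA_real_)
            },
            kbac = {
                grp <- kbacGroups(G, mafThreshold)
                sigma <- stats::sd(e)
                tObs <- kbacFromGroups(e, grp, sigma)
                S <- rowsum(E, grp$id)                       # K x B sums
                M <- S / grp$sizes
                W <- stats::pnorm(M * sqrt(grp$sizes) / sigma)
                contrib <- W * M * grp$sizes
                if (!is.na(grp$refGroup))
                    contrib <- contrib[-grp$refGroup, , drop = FALSE]
                tPerm <- colSums(contrib)
                data.frame(test = "kbac", statistic = tObs,
                           p_empirical = permPFromDraws(tObs, tPerm,
                                                        "two-sided"),
                           p_analytic = NA_real_, n_perm = B,
                           vt_threshold = NA_real_)
            })
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Analytic p-value for the kernel statistic
#'
#' Null tail probability of \eqn{Q = \sum_j w_j (e' g_j)^2} under
#' exchangeable residuals: a mixture of chi-squares
#' \eqn{\sum_k \lambda_k \chi^2_1} with \eqn{\lambda_k} the eigenvalues
#' of \eqn{\hat\sigma^2 W^{1/2} G_c' G_c W^{1/2}} (\eqn{G_c}
#' column-centered, \eqn{\hat\sigma^2} the residual variance).
#' Evaluated by Imhof's characteristic-function inversion; if the
#' numerical integration fails, falls back to Liu-Tang-Zhang moment
#' matching with a warning.
#'
#' @param Q observed statistic.
#' @param e residual vector.
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param weights SKAT weight scheme (see \code{\link{skatStatistic}}).
#' @param mafThreshold inclusion threshold.
#' @return upper-tail probability in (0, 1].
#' @export
skatAnalyticP <- function(Q, e, G, weights = "madsen-browning",
                          mafThreshold = 0.01) {
    if (is(e, "NullFit")) e <- residuals(e)
    if (Q <= 0) return(1)
    j <- qualifyingSites(G, mafThreshold)
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g", mafThreshold))
    w <- resolveSkatWeights(G, j, weights)
    cnt <- genotypeCounts(G)[, j, drop = FALSE]
    Gc <- sweep(cnt, 2L, colMeans(cnt))
    M <- sweep(Gc, 2L, sqrt(w), "*")
    lambda <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    lambda <- lambda[lambda > max(lambda) * 1e-12] * stats::var(e)
    if (length(lambda) == 1L)            # exact: a scaled chi-square(1)
        return(min(max(stats::pchisq(Q / lambda, 1, lower.tail = FALSE),
                       1e-15), 1))
    p <- tryCatch(imhofTail(Q, lambda), error = function(err) NA_real_)
    if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) {
        warning("characteristic-function inversion failed; ",
                "using moment-matching approximation")
        p <- liuTail(Q, lambda)
    }
    min(max(p, 1e-15), 1)
}

# Imhof (1961) numerical inversion for P(sum lambda_k chi2_1 > x).
imhofTail <- function(x, lambda) {
    integrand <- function(u) {
        theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * x * u
        rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
        val <- sin(theta) / (u * rho)
        val[u == 0] <- 0.5 * (sum(lambda) - x)
        val
    }
    0.5 + stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                           subdivisions = 500L)$value / pi
}

# Liu-Tang-Zhang three-moment chi-square approximation.
liuTail <- function(x, lambda) {
    c1 <- sum(lambda); c2 <- sum(lambda^2)
    c3 <- sum(lambda^3); c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5
    s2 <- c4 / c2^2
    if (s1^2 > s2) {
        a <- 1 / (s1 - sqrt(s1^2 - s2))
        delta <- s1 * a^3 - a^2
        l <- a^2 - 2 * delta
    } else {
        delta <- 0
        l <- c2^3 / c3^2
    }
    tStar <- (x - c1) / sqrt(2 * c2)
    xStar <- tStar * sqrt(2) * sqrt(l + 2 * delta) + l + delta
    stats::pchisq(xStar, df = l, ncp = delta, lower.tail = FALSE)
}

#' Normal-approximation p-value for a burden score
#'
#' Two-sided tail of \eqn{U/\sqrt{\mathrm{Var}_\pi(U)}} with the exact
#' permutation variance
#' \eqn{\mathrm{Var}_\pi(U) = S_e S_x / (n - 1)}. Approximate: the
#' normal limit can be violated at low aggregate allele counts, where
#' the permutation p-value is preferred.
#'
#' @param U observed score.
#' @param e residual vector.
#' @param coding \code{\linkS4class{GenotypeCoding}} or numeric vector.
#' @return two-sided p-value.
#' @export
burdenAnalyticP <- function(U, e, coding) {
    if (is(e, "NullFit")) e <- residuals(e)
    x <- if (is(coding, "GenotypeCoding")) coding@x else coding
    n <- length(e)
    v <- sum((e - mean(e))^2) * sum((x - mean(x))^2) / (n - 1)
    if (v <= 0) {
        warning("zero permutation variance: p = 1")
        return(1)
    }
    2 * stats::pnorm(-abs(U) / sqrt(v))
}
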