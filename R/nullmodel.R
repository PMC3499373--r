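# Ascertainment-corrected null model.
#
# The null fit is factorized: (i) a two-sided truncated-normal maximum
# likelihood fit of the primary trait, which carries all of the
# ascertainment information, then (ii) ordinary least squares of the
# secondary trait on the primary-trait residual, which is unaffected by
# selection because the conditional law of y2 given y1 does not depend
# on the ascertainment indicator. The secondary-trait residuals of the
# second stage are approximately normal and exchangeable under the null.

#' Truncated-normal fit of the primary trait in a selected sample
#'
#' Maximizes \deqn{\prod_i \frac{\phi((y_{1i} - \mu_i)/\sigma_1)/\sigma_1}
#'   {\Phi((l - \mu_i)/\sigma_1) + 1 - \Phi((u - \mu_i)/\sigma_1)}}
#' over \eqn{(\gamma_1, \beta_p, \log\sigma_1)}, where
#' \eqn{\mu_i = X_{1i}\gamma_1 + \beta_p x_i} and \eqn{(l, u)} are the
#' two-sided tail cuts of the selection region. The denominator is the
#' probability of ascertainment, evaluated with complementary-CDF terms
#' on the log scale to avoid cancellation at extreme cuts. Quasi-Newton
#' (BFGS) from OLS starting values; a flagged non-convergence triggers a
#' derivative-free (Nelder-Mead) restart.
#'
#' @param y1 primary-trait values of the selected individuals.
#' @param X1 optional covariate matrix (no intercept column).
#' @param coding genotype coding entering the primary-trait mean (the
#'   nuisance genetic effect): a per-individual scalar coding (numeric
#'   vector or \code{\linkS4class{GenotypeCoding}}), a matrix with one
#'   column per variant (the multivariate per-variant option), or
#'   \code{NULL}. Constant (and, for matrices, aliased) columns are
#'   dropped; a fully degenerate coding is reported as \code{NA}.
#' @param region a \code{\linkS4class{SelectionRegion}}, or \code{NULL}
#'   for an unascertained (randomly sampled) dataset, in which case the
#'   fit reduces to ordinary least squares.
#' @param reltol optimizer convergence tolerance.
#' @return list with \code{gamma1}, \code{betaP}, \code{sigma1},
#'   \code{loglik}, \code{converged}, and the fitted means \code{mu1}.
#' @export
fitTruncatedPrimary <- function(y1, X1 = NULL, coding = NULL, region = NULL,
                                reltol = 1e-10) {
    n <- length(y1)
    D <- cbind(`(Intercept)` = rep(1, n), if (!is.null(X1)) as.matrix(X1))
    kBase <- ncol(D)
    nCoding <- 0L
    if (!is.null(coding)) {
        if (is(coding, "GenotypeCoding")) coding <- coding@x
        coding <- as.matrix(coding)
        if (nrow(coding) != n) stop("'coding' rows must match 'y1'")
        keep <- apply(coding, 2L, stats::sd) > 0
        coding <- coding[, keep, drop = FALSE]
        if (ncol(coding)) {
            # drop columns aliased with the design so far
            q <- qr(cbind(D, coding))
            full <- q$pivot[seq_len(q$rank)]
            coding <- coding[, full[full > kBase] - kBase, drop = FALSE]
        }
        if (ncol(coding) == 0L)
            message("degenerate genotype coding: beta_p dropped as ",
                    "non-identifiable")
        else D <- cbind(D, coding)
        nCoding <- ncol(coding)
    }
    k <- ncol(D)
    truncated <- !is.null(region)
    if (truncated) {
        if (!all(inRegion(region, y1)))
            stop("some selected individuals lie outside the selection region")
        lo <- region@lowerCut
        hi <- region@upperCut
    }
    ols <- stats::lm.fit(D, y1)
    sigma0 <- sqrt(mean(ols$residuals^2))
    theta0 <- c(ols$coefficients, log(sigma0))

    nll <- function(theta) {
        mu <- as.vector(D %*% theta[seq_len(k)])
        s <- exp(theta[k + 1L])
        ll <- stats::dnorm(y1, mu, s, log = TRUE)
        if (truncated)
            ll <- ll - logspaceAdd(
                stats::pnorm(lo, mu, s, log.p = TRUE),
                stats::pnorm(hi, mu, s, lower.tail = FALSE, log.p = TRUE))
        val <- -sum(ll)
        if (!is.finite(val)) val <- .Machine$double.xmax / 1e10
        val
    }
    # analytic gradient of the negative log-likelihood in
    # (beta, log sigma); the ascertainment-probability terms use
    # log-scale normal quantities to stay stable at extreme cuts
    gr <- function(theta) {
        mu <- as.vector(D %*% theta[seq_len(k)])
        s <- exp(theta[k + 1L])
        z <- (y1 - mu) / s
        dMu <- z / s
        dT <- z^2 - 1
        if (truncated) {
            a <- (lo - mu) / s
            b <- (hi - mu) / s
            logPA <- logspaceAdd(
                stats::pnorm(a, log.p = TRUE),
                stats::pnorm(b, lower.tail = FALSE, log.p = TRUE))
            phiA <- exp(stats::dnorm(a, log = TRUE) - logPA)
            phiB <- exp(stats::dnorm(b, log = TRUE) - logPA)
            dMu <- dMu + (phiA - phiB) / s
            dT <- dT + a * phiA - b * phiB
        }
        -c(as.vector(crossprod(D, dMu)), sum(dT))
    }
    fit <- stats::optim(theta0, nll, gr, method = "BFGS",
                        control = list(maxit = 1000, reltol = reltol))
    converged <- fit$convergence == 0L
    if (!converged) {
        fit2 <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                             control = list(maxit = 5000, reltol = reltol))
        if (fit2$value <= fit$value) fit <- fit2
        converged <- fit$convergence == 0L
    }
    sigma1 <- exp(fit$par[k + 1L])
    if (sigma1 < 1e-6 * stats::sd(y1))
        stop("sigma1 driven to the boundary: truncated fit is degenerate")
    beta <- fit$par[seq_len(k)]
    list(gamma1 = unname(beta[seq_len(k - nCoding)]),
         betaP = if (nCoding) unname(beta[seq.int(k - nCoding + 1L, k)])
                 else NA_real_,
         sigma1 = unname(sigma1),
         loglik = -fit$value,
         converged = converged,
         mu1 = as.vector(D %*% beta))
}

#' Conditional least-squares fit of the secondary trait
#'
#' OLS of \eqn{y_2} on an intercept, optional covariates, and the
#' primary-trait residual \eqn{y_1 - \hat\mu_1}. Because selection acts
#' only through \eqn{y_1}, this conditional regression is correctly
#' specified in the ascertained sample; the coefficient of the residual
#' is consistent for \eqn{\rho\sigma_2/\sigma_1} and the fit residuals
#' are exchangeable under the null of no secondary-trait association.
#'
#' @param y2 secondary-trait values of the selected individuals.
#' @param X2 optional covariate matrix (no intercept column).
#' @param y1 primary-trait values.
#' @param mu1Hat fitted primary means from
#'   \code{\link{fitTruncatedPrimary}}.
#' @return list with \code{gamma2}, \code{tau}, \code{sigmaCond} and the
#'   residual vector \code{residuals}.
#' @export
fitConditionalSecondary <- function(y2, X2 = NULL, y1, mu1Hat) {
    n <- length(y2)
    if (length(y1) != n || length(mu1Hat) != n)
        stop("'y2', 'y1' and 'mu1Hat' lengths differ")
    D <- cbind(`(Intercept)` = rep(1, n), if (!is.null(X2)) as.matrix(X2),
               primaryResidual = y1 - mu1Hat)
    q <- qr(D)
    if (q$rank < ncol(D)) {
        bad <- colnames(D)[q$pivot[seq.int(q$rank + 1L, ncol(D))]]
        stop("collinear columns in the secondary-trait design: ",
             paste(bad, collapse = ", "))
    }
    fit <- stats::lm.fit(D, y2)
    cf <- fit$coefficients
    list(gamma2 = unname(cf[seq_len(ncol(D) - 1L)]),
         tau = unname(cf[ncol(D)]),
         sigmaCond = sqrt(sum(fit$residuals^2) / (n - ncol(D))),
         residuals = unname(fit$residuals))
}

#' Exchangeable secondary-trait residuals under ascertainment
#'
#' Composes \code{\link{fitTruncatedPrimary}} and
#' \code{\link{fitConditionalSecondary}}. The residuals can be analyzed
#' by any rare-variant association test with permutation inference.
#'
#' @param y1,y2 primary and secondary trait values of the selected
#'   individuals.
#' @param X1,X2 optional covariate matrices.
#' @param G optional \code{\linkS4class{GenotypeMatrix}} of the selected
#'   individuals, used to build the default nuisance coding
#'   (Madsen-Browning weighted counts, MAF <= 1\%) when
#'   \code{primaryCoding} is \code{NULL}.
#' @param primaryCoding scalar coding of the region genotype entering
#'   the primary-trait null mean (a numeric vector or a
#'   \code{\linkS4class{GenotypeCoding}}).
#' @param region the \code{\linkS4class{SelectionRegion}} (or
#'   \code{NULL} for random sampling).
#' @param reltol optimizer tolerance for the truncated fit.
#' @return a \code{\linkS4class{NullFit}}.
#' @export
computeResiduals <- function(y1, y2, X1 = NULL, X2 = NULL, G = NULL,
                             primaryCoding = NULL, region = NULL,
                             reltol = 1e-10) {
    if (is.null(primaryCoding) && !is.null(G))
        primaryCoding <- codeWSS(G)
    f1 <- fitTruncatedPrimary(y1, X1, primaryCoding, region,
                              reltol = reltol)
    f2 <- fitConditionalSecondary(y2, X2, y1, f1$mu1)
    new("NullFit",
        gamma1 = f1$gamma1, betaP = f1$betaP, sigma1 = f1$sigma1,
        gamma2 = f2$gamma2, tau = f2$tau, sigmaCond = f2$sigmaCond,
        converged = f1$converged, loglik = f1$loglik,
        residuals = f2$residuals)
}

#' Large-sample bias of naive secondary-trait analysis
#'
#' Expected bias of the ordinary (ascertainment-ignoring) least-squares
#' slope of the secondary trait on an aggregate genotype coding, in a
#' sample selected on the two tails of the primary trait. Computed under
#' a Gaussian working model for the coding (justified by the CLT for
#' aggregated rare-variant codings): with \eqn{x \sim N(0, v)},
#' \eqn{y_1 = \beta_p x + \epsilon_1}, selection at the \code{qLow} and
#' \code{qHigh} marginal quantiles of \eqn{y_1}, and no true secondary
#' effect, the bias is
#' \deqn{\rho\frac{\sigma_2}{\sigma_1}\left(
#'   \frac{\mathrm{Cov}_A(x, y_1)}{\mathrm{Var}_A(x)} - \beta_p\right),}
#' where the ascertained moments follow from the truncated bivariate
#' normal and are evaluated by numerical integration. The bias is odd in
#' \eqn{\rho}, vanishes when either \eqn{\rho = 0} or \eqn{\beta_p = 0},
#' and is approximately linear in \eqn{\beta_p} when the primary effect
#' is small.
#'
#' Two standard but insufficient adjustments can also be evaluated:
#' \code{"tail_indicator"} adds a high/low-tail indicator covariate to
#' the naive regression; \code{"tail_meta"} analyzes the two tails
#' separately and combines by precision weighting. Both retain a
#' non-zero asymptotic bias whenever \eqn{\beta_p \ne 0} and
#' \eqn{\rho \ne 0}.
#'
#' @param betaP true primary-trait effect on the coding.
#' @param rho residual correlation of the two traits.
#' @param qLow,qHigh selection tail quantiles of the primary trait.
#' @param codingVariance variance of the genotype coding.
#' @param sigma1,sigma2 residual SDs (default 1).
#' @param adjustment \code{"none"}, \code{"tail_indicator"} or
#'   \code{"tail_meta"}.
#' @return the asymptotic bias (a scalar).
#' @export
naiveBias <- function(betaP, rho, qLow, qHigh, codingVariance,
                      sigma1 = 1, sigma2 = 1,
                      adjustment = c("none", "tail_indicator", "tail_meta")) {
    adjustment <- match.arg(adjustment)
    stopIfNotScalarFraction(qLow, "qLow")
    stopIfNotScalarFraction(qHigh, "qHigh")
    if (!(qLow < qHigh)) stop("'qLow' must be below 'qHigh'")
    if (codingVariance <= 0) stop("'codingVariance' must be positive")
    v <- codingVariance
    V <- betaP^2 * v + sigma1^2          # marginal variance of y1
    sdY <- sqrt(V)
    cLo <- stats::qnorm(qLow, 0, sdY)
    cHi <- stats::qnorm(qHigh, 0, sdY)
    mom <- function(pow, from, to)
        stats::integrate(function(x) x^pow * stats::dnorm(x, 0, sdY),
                         from, to, rel.tol = 1e-10)$value
    a <- betaP * v / V                   # E[x | y1] = a y1
    condVarX <- v - a^2 * V              # Var(x | y1)
    tailMoments <- function(from, to) {
        p <- mom(0, from, to)
        m1 <- mom(1, from, to) / p
        m2 <- mom(2, from, to) / p
        list(p = p, mean = m1, var = m2 - m1^2)
    }
    lowT <- tailMoments(-Inf, cLo)
    highT <- tailMoments(cHi, Inf)
    pSel <- lowT$p + highT$p
    wLow <- lowT$p / pSel
    wHigh <- highT$p / pSel
    biasFromY1Moments <- function(varY1A) {
        covXY <- a * varY1A
        varX <- a^2 * varY1A + condVarX
        rho * (sigma2 / sigma1) * (covXY / varX - betaP)
    }
    if (adjustment == "none") {
        m1A <- wLow * lowT$mean + wHigh * highT$mean
        m2A <- wLow * (lowT$var + lowT$mean^2) +
               wHigh * (highT$var + highT$mean^2)
        return(biasFromY1Moments(m2A - m1A^2))
    }
    if (adjustment == "tail_indicator") {
        # within-tail (pooled) moments: tail means are absorbed by the
        # indicator, leaving the within-tail covariance structure
        varW <- wLow * lowT$var + wHigh * highT$var
        return(biasFromY1Moments(varW))
    }
    # tail_meta: per-tail slopes combined with precision weights
    # proportional to tail mass times the tail variance of x
    bLow <- biasFromY1Moments(lowT$var)
    bHigh <- biasFromY1Moments(highT$var)
    precLow <- wLow * (a^2 * lowT$var + condVarX)
    precHigh <- wHigh * (a^2 * highT$var + condVarX)
    (precLow * bLow + precHigh * bHigh) / (precLow + precHigh)
}
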