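#' Select causal-site sets for the two traits
#'
#' Among sites under purifying selection (selection coefficient
#' \eqn{s > 10^{-4}}, the causal-eligible pool), a fraction is chosen at
#' random to be causal for the primary trait, and an independently chosen
#' fraction to be causal for the secondary trait. Sites in the
#' intersection are pleiotropic. Each set has
#' \code{floor(proportion * n_eligible)} members.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}} whose site table has
#'   selection coefficients.
#' @param proportion fraction in (0, 1] of eligible sites per causal set.
#' @param seed integer seed or \code{NULL}.
#' @return \code{G} with \code{causal_primary} / \code{causal_secondary}
#'   flags set in its site table.
#' @export
selectCausalSets <- function(G, proportion, seed = NULL) {
    stopIfNotScalarFraction(proportion, "proportion", openHigh = FALSE)
    sites <- siteInfo(G)
    eligible <- which(!is.na(sites$sel_coeff) & sites$sel_coeff > 1e-4)
    if (!length(eligible))
        stop("no causal-eligible sites: none with sel_coeff > 1e-4")
    k <- floor(proportion * length(eligible))
    withSeed(seed, {
        cp <- sample(eligible, k)
        cs <- sample(eligible, k)
        sites$causal_primary <- seq_len(nrow(sites)) %in% cp
        sites$causal_secondary <- seq_len(nrow(sites)) %in% cs
    })
    G@sites <- sites
    G
}

#' Per-site effect sizes for causal variants
#'
#' Effect magnitudes are inversely related to MAF:
#' \eqn{|\beta_j| = c_1 + c_2 |\log_{10} p_j|} for causal site \eqn{j}
#' (model \code{"log-maf"}); \code{c2 = 0} (model \code{"fixed"})
#' recovers a constant magnitude \eqn{c_1}. A fraction
#' \code{fracPositive} of the causal sites (rounded to the nearest
#' integer count) receives positive sign; which sites is decided at
#' random under \code{seed}. Non-causal sites get exactly 0.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}} with causal flags set
#'   (see \code{\link{selectCausalSets}}).
#' @param trait \code{"primary"} or \code{"secondary"}: which causal flag
#'   to use.
#' @param model \code{"fixed"} or \code{"log-maf"}.
#' @param c1,c2 magnitude parameters (trait-SD units per minor allele);
#'   \code{c2} is ignored under \code{"fixed"}.
#' @param fracPositive fraction of causal sites with positive effect.
#' @param seed integer seed or \code{NULL}.
#' @return numeric effect vector, one entry per site.
#' @export
effectSizes <- function(G, trait = c("primary", "secondary"),
                        model = c("fixed", "log-maf"),
                        c1, c2 = 0, fracPositive = 1, seed = NULL) {
    trait <- match.arg(trait)
    model <- match.arg(model)
    if (!is.numeric(c1) || c1 < 0) stop("'c1' must be non-negative")
    stopIfNotScalarFraction(fracPositive, "fracPositive",
                            openLow = FALSE, openHigh = FALSE)
    sites <- siteInfo(G)
    causal <- which(if (trait == "primary") sites$causal_primary
                    else sites$causal_secondary)
    beta <- numeric(nrow(sites))
    if (!length(causal)) return(beta)
    mag <- if (model == "fixed") rep(c1, length(causal))
           else c1 + c2 * abs(log10(sites$maf[causal]))
    nPos <- round(fracPositive * length(causal))
    sgn <- rep(-1, length(causal))
    withSeed(seed, sgn[sample(length(causal), nPos)] <- 1)
    beta[causal] <- sgn * mag
    beta
}

#' Simulate bivariate-normal primary and secondary traits
#'
#' \deqn{y_{1i} = X_{1i}\gamma_1 + \sum_j \beta_{p,j} g_{ij} +
#'   \epsilon_{1i}, \qquad
#'   y_{2i} = X_{2i}\gamma_2 + \sum_j \beta_{s,j} g_{ij} +
#'   \epsilon_{2i},}
#' with \eqn{(\epsilon_1, \epsilon_2)} bivariate normal, SDs
#' \eqn{(\sigma_1, \sigma_2)} and correlation \eqn{\rho}.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param betaPrimary,betaSecondary per-site effect vectors (see
#'   \code{\link{effectSizes}}).
#' @param rho residual correlation in [-1, 1].
#' @param sigma1,sigma2 positive residual SDs.
#' @param X1,X2 optional covariate matrices (no intercept column).
#' @param gamma1,gamma2 covariate coefficient vectors matching
#'   \code{X1}/\code{X2}.
#' @param seed integer seed or \code{NULL}.
#' @return \code{data.frame} with columns \code{y1}, \code{y2} and any
#'   covariates (\code{cov_*}).
#' @export
simulateTraits <- function(G, betaPrimary = NULL, betaSecondary = NULL,
                           rho = 0, sigma1 = 1, sigma2 = 1,
                           X1 = NULL, X2 = NULL,
                           gamma1 = NULL, gamma2 = NULL, seed = NULL) {
    n <- nIndividuals(G)
    m <- nSites(G)
    if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
    if (sigma1 <= 0 || sigma2 <= 0) stop("residual SDs must be positive")
    chk <- function(beta, name) {
        if (is.null(beta)) return(numeric(m))
        if (length(beta) != m)
            stop(sprintf("'%s' must have one entry per site (%d)", name, m))
        beta
    }
    betaPrimary <- chk(betaPrimary, "betaPrimary")
    betaSecondary <- chk(betaSecondary, "betaSecondary")
    covPart <- function(X, gamma, name) {
        if (is.null(X)) return(numeric(n))
        X <- as.matrix(X)
        if (nrow(X) != n) stop(sprintf("'%s' rows must match individuals", name))
        if (is.null(gamma) || length(gamma) != ncol(X))
            stop(sprintf("coefficients for '%s' missing or wrong length", name))
        as.vector(X %*% gamma)
    }
    mu1 <- covPart(X1, gamma1, "X1")
    mu2 <- covPart(X2, gamma2, "X2")
    cn <- genotypeCounts(G)
    ip <- which(betaPrimary != 0)
    is_ <- which(betaSecondary != 0)
    if (length(ip))
        mu1 <- mu1 + as.vector(cn[, ip, drop = FALSE] %*% betaPrimary[ip])
    if (length(is_))
        mu2 <- mu2 + as.vector(cn[, is_, drop = FALSE] %*% betaSecondary[is_])
    withSeed(seed, {
        e1 <- stats::rnorm(n)
        e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
        out <- data.frame(y1 = mu1 + sigma1 * e1, y2 = mu2 + sigma2 * e2)
        if (!is.null(X1)) {
            X1 <- as.matrix(X1)
            colnames(X1) <- paste0("cov_", seq_len(ncol(X1)))
            out <- cbind(out, X1)
        }
        out
    })
}

#' Adjust medicated blood-pressure measurements
#'
#' Adds a fixed offset to the trait value of treated individuals (e.g.
#' +10 mm Hg systolic, +5 mm Hg diastolic for individuals on
#' antihypertensive medication) so that treated and untreated values are
#' comparable.
#'
#' @param bp numeric trait vector.
#' @param medicated logical vector, same length.
#' @param delta offset added to medicated entries.
#' @return adjusted vector.
#' @export
adjustMedication <- function(bp, medicated, delta) {
    if (length(bp) != length(medicated))
        stop("'bp' and 'medicated' lengths differ")
    bp + delta * as.numeric(medicated)
}

#' Covariate-adjusted quantile normalization
#'
#' Residuals of an OLS fit of the trait on an intercept plus the supplied
#' covariates are mapped to normal scores
#' \eqn{\Phi^{-1}((r_i - 0.5)/n)}, with tied residuals receiving average
#' ranks. The result has mean near 0 and variance near 1.
#'
#' @param trait numeric vector.
#' @param covariates optional matrix/data.frame of covariates (no
#'   intercept column).
#' @return normal-scores vector, same length as \code{trait}.
#' @export
covariateAdjustQuantileNormalize <- function(trait, covariates = NULL) {
    n <- length(trait)
    X <- cbind(`(Intercept)` = rep(1, n), if (!is.null(covariates))
        as.matrix(covariates))
    if (n <= ncol(X)) stop("need more observations than covariates")
    q <- qr(X)
    if (q$rank < ncol(X))
        stop("covariate matrix is rank deficient (collinear columns)")
    res <- stats::residuals(stats::lm.fit(X, trait))
    stats::qnorm((rank(res, ties.method = "average") - 0.5) / n)
}
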