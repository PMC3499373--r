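# Simulation harness for type-I-error, power and meta-analysis
# experiments: per replicate, a rare-variant region and bivariate traits
# are simulated for a cohort, the extreme tails are selected, the
# ascertainment-corrected null model is fitted per nuisance coding, and
# the region tests are evaluated by permutation.

#' Experiment configuration
#'
#' Defines one study scenario. Defaults mirror the standard design:
#' 5,000 individuals with extreme primary-trait values selected from a
#' cohort of 100,000; a 200-site region drawn from a growth-skewed SFS
#' on [2e-5, 0.05]; 50\% of causal-eligible sites causal per trait.
#' \code{betaPrimary}/\code{betaSecondary} are the magnitude parameters
#' \eqn{c_1} of the per-trait effect models (0 = no association).
#'
#' @param cohortN,selectN cohort size and number selected.
#' @param replicates,permutations Monte-Carlo sizes.
#' @param alpha nominal significance level.
#' @param nSites sites per simulated region (before monomorphic
#'   filtering).
#' @param spectrum SFS shape (see \code{\link{sfsConfig}}).
#' @param mafMin,mafMax SFS range.
#' @param causalProportion fraction of eligible sites causal per trait.
#' @param betaPrimary,betaSecondary effect magnitudes \eqn{c_1}; signed
#'   (a negative value gives unidirectional negative effects).
#' @param c2Primary,c2Secondary MAF-dependent magnitude slopes
#'   (\code{"log-maf"} model when non-zero).
#' @param fracPositiveSecondary fraction of secondary-causal sites with
#'   positive effect (0.8 gives the 80/20 bidirectional scenario).
#' @param rho trait residual correlation.
#' @param tests region tests to run.
#' @param mafThreshold,vtCap MAF cutoffs for fixed-threshold tests and
#'   VT.
#' @param residualMethod \code{"corrected"} for the ascertainment-corrected
#'   residuals, \code{"naive"} for residuals that ignore the sampling
#'   mechanism (used to demonstrate type-I inflation).
#' @param nuisance nuisance primary-trait coding in the null fit:
#'   \code{"maf-bins"} (per-frequency-stratum counts, one fit shared by
#'   all tests; the default), \code{"per-test"} (one scalar coding per
#'   test family) or \code{"per-variant"} (one nuisance effect per
#'   site).
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @return a validated list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(cohortN = 100000, selectN = 5000,
                             replicates = 500, permutations = 500,
                             alpha = 0.05, nSites = 200,
                             spectrum = "growth",
                             mafMin = 2e-5, mafMax = 0.05,
                             causalProportion = 0.5,
                             betaPrimary = 0, betaSecondary = 0,
                             c2Primary = 0, c2Secondary = 0,
                             fracPositiveSecondary = 1, rho = 0,
                             tests = c("cmc", "wss", "kbac", "vt", "skat"),
                             mafThreshold = 0.01, vtCap = 0.05,
                             residualMethod = c("corrected", "naive"),
                             nuisance = c("maf-bins", "per-test",
                                          "per-variant"),
                             seed = 1) {
    residualMethod <- match.arg(residualMethod)
    nuisance <- match.arg(nuisance)
    tests <- match.arg(tests, c("cmc", "wss", "kbac", "vt", "skat"),
                       several.ok = TRUE)
    if (selectN > cohortN) stop("selectN must not exceed cohortN")
    stopIfNotScalarFraction(alpha, "alpha")
    if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
    structure(as.list(environment()), class = "ExperimentConfig")
}

# One simulated study: region, traits, tail selection. Consumes the
# ambient RNG stream (seed handling is the caller's).
simulateStudy <- function(cfg) {
    mafs <- drawSiteFrequencies(sfsConfig(cfg$nSites, cfg$spectrum,
                                          cfg$mafMin, cfg$mafMax))
    s <- assignSelectionCoeffs(mafs)
    G <- sampleGenotypes(mafs, cfg$cohortN, selCoeff = s)
    G <- selectCausalSets(G, cfg$causalProportion)
    betaP <- effectSizes(G, "primary",
                         model = if (cfg$c2Primary != 0) "log-maf"
                                 else "fixed",
                         c1 = abs(cfg$betaPrimary), c2 = cfg$c2Primary,
                         fracPositive = if (cfg$betaPrimary < 0) 0 else 1)
    betaS <- effectSizes(G, "secondary",
                         model = if (cfg$c2Secondary != 0) "log-maf"
                                 else "fixed",
                         c1 = abs(cfg$betaSecondary), c2 = cfg$c2Secondary,
                         fracPositive = if (cfg$betaSecondary < 0)
                             1 - cfg$fracPositiveSecondary
                             else cfg$fracPositiveSecondary)
    ph <- simulateTraits(G, betaP, betaS, rho = cfg$rho)
    asc <- selectExtremes(ph$y1, cfg$selectN)
    list(G = G[asc@indices, ], y1 = ph$y1[asc@indices],
         y2 = ph$y2[asc@indices], region = asc@region)
}

# Analyze one ascertained study, then run permutation tests. The
# nuisance primary-trait coding in the null fit is either one scalar
# coding per test family ("per-test": the test's own coding for burden
# tests, Madsen-Browning weighted counts for SKAT/KBAC) or a single
# multivariate per-variant fit shared by every test ("per-variant").
# Returns the regionTests data frame.
analyzeStudy <- function(study, cfg) {
    n <- length(study$y2)
    perm <- vapply(seq_len(cfg$permutations), function(b) sample.int(n),
                   integer(n))
    if (cfg$residualMethod == "naive") {
        e <- study$y2 - mean(study$y2)
        return(regionTests(e, study$G, tests = cfg$tests, perm = perm,
                           mafThreshold = cfg$mafThreshold,
                           vtCap = cfg$vtCap))
    }
    if (cfg$nuisance %in% c("maf-bins", "per-variant")) {
        coding <- if (cfg$nuisance == "maf-bins") {
            cap <- max(cfg$vtCap, cfg$mafThreshold)
            inner <- c(5e-5, 1e-4, 2e-4, 4e-4, 1e-3, 1e-2)
            codeMafBins(study$G,
                        breaks = c(0, inner[inner < cap], cap))
        } else {
            j <- qualifyingSites(study$G,
                                 max(cfg$vtCap, cfg$mafThreshold))
            genotypeCounts(study$G)[, j, drop = FALSE]
        }
        fit <- computeResiduals(study$y1, study$y2, G = study$G,
                                primaryCoding = coding,
                                region = study$region, reltol = 1e-8)
        return(regionTests(residuals(fit), study$G, tests = cfg$tests,
                           perm = perm,
                           mafThreshold = cfg$mafThreshold,
                           vtCap = cfg$vtCap))
    }
    groups <- list(
        cmc = intersect(cfg$tests, "cmc"),
        wss = intersect(cfg$tests, c("wss", "skat", "kbac")),
        vt = intersect(cfg$tests, "vt"))
    out <- lapply(names(groups), function(gname) {
        tst <- groups[[gname]]
        if (!length(tst)) return(NULL)
        coding <- switch(gname,
            cmc = codeCMC(study$G, cfg$mafThreshold),
            wss = codeWSS(study$G, cfg$mafThreshold),
            vt = codeCount(study$G, cfg$vtCap))
        fit <- computeResiduals(study$y1, study$y2, G = study$G,
                                primaryCoding = coding,
                                region = study$region, reltol = 1e-8)
        regionTests(residuals(fit), study$G, tests = tst, perm = perm,
                    mafThreshold = cfg$mafThreshold, vtCap = cfg$vtCap)
    })
    res <- do.call(rbind, out)
    res[match(cfg$tests, res$test), , drop = FALSE]
}

makeReport <- function(pvalues, cfg, extra = list()) {
    rate <- colMeans(pvalues <= cfg$alpha)
    structure(c(list(
        rejection = rate,
        se = sqrt(rate * (1 - rate) / nrow(pvalues)),
        alpha = cfg$alpha,
        replicates = nrow(pvalues),
        pvalues = pvalues,
        config = cfg), extra),
        class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
    cat(sprintf("ExperimentReport: %d replicates, alpha = %g\n",
                x$replicates, x$alpha))
    tab <- rbind(rejection = x$rejection, se = x$se)
    print(round(tab, 4))
    invisible(x)
}

#' Type-I-error experiment
#'
#' Simulates the null of no secondary-trait association (the gene may
#' still affect the primary trait), runs every configured test per
#' replicate, and reports rejection rates at \code{alpha}.
#'
#' @param cfg an \code{\link{experimentConfig}} with zero secondary
#'   effects.
#' @return an \code{ExperimentReport}: per-test rejection rates,
#'   binomial SEs, and the full p-value matrix (for QQ plots).
#' @export
runTypeIError <- function(cfg) {
    if (cfg$betaSecondary != 0 || cfg$c2Secondary != 0)
        stop("type-I configuration requires zero secondary-trait effects")
    P <- replicateLoop(cfg)
    makeReport(P, cfg)
}

#' Power experiment
#'
#' As \code{\link{runTypeIError}} but under a configured secondary-trait
#' effect; refuses a null configuration.
#'
#' @param cfg an \code{\link{experimentConfig}} with non-zero secondary
#'   effects.
#' @return an \code{ExperimentReport}.
#' @export
runPower <- function(cfg) {
    if (cfg$betaSecondary == 0 && cfg$c2Secondary == 0)
        stop("power configuration requires a non-zero secondary-trait ",
             "effect (use runTypeIError for the null)")
    P <- replicateLoop(cfg)
    makeReport(P, cfg)
}

replicateLoop <- function(cfg) {
    P <- matrix(NA_real_, cfg$replicates, length(cfg$tests),
                dimnames = list(NULL, cfg$tests))
    for (r in seq_len(cfg$replicates)) {
        P[r, ] <- withSeed(cfg$seed + r, {
            study <- simulateStudy(cfg)
            analyzeStudy(study, cfg)$p_empirical
        })
    }
    P
}

#' Three-study meta-analysis experiment
#'
#' Simulates a meta-analysis of studies whose primary traits differ but
#' that share the secondary trait: per replicate each study is
#' simulated, ascertained and analyzed independently, per-study
#' p-values are transformed to Z and combined weighted by the square
#' root of the sample sizes, and rejection rates are reported per study
#' and for the meta-analysis.
#'
#' The default follows the standard three-study design: each study
#' selects 2,500 extremes from its own pool of 50,000; primary-trait
#' effects and trait correlations are (-0.5, 0.6), (0.25, 0.4) and
#' (none, -0.2).
#'
#' @param studies list of three (or more)
#'   \code{\link{experimentConfig}}s; the secondary-trait scenario
#'   should match across studies.
#' @param replicates,permutations,alpha Monte-Carlo sizes and level.
#' @param seed base seed.
#' @return an \code{ExperimentReport} whose \code{rejection} is a
#'   matrix (tests x studies + meta) and with p-value arrays per study
#'   and combined.
#' @export
runMetaExperiment <- function(studies = defaultMetaStudies(),
                              replicates = 500, permutations = 500,
                              alpha = 0.05, seed = 1) {
    nStudy <- length(studies)
    if (nStudy < 1) stop("need at least one study")
    tests <- studies[[1]]$tests
    studies <- lapply(studies, function(s) {
        s$permutations <- permutations
        s
    })
    directionalTests <- c("cmc", "wss", "single")
    Pstudy <- array(NA_real_, c(replicates, length(tests), nStudy),
                    dimnames = list(NULL, tests,
                                    paste0("study", seq_len(nStudy))))
    Pmeta <- matrix(NA_real_, replicates, length(tests),
                    dimnames = list(NULL, tests))
    for (r in seq_len(replicates)) {
        withSeed(seed + r, {
            perStudy <- lapply(studies, function(s)
                analyzeStudy(simulateStudy(s), s))
            for (s in seq_len(nStudy))
                Pstudy[r, , s] <- perStudy[[s]]$p_empirical
            for (t in seq_along(tests)) {
                directional <- tests[t] %in% directionalTests
                cz <- combineZ(
                    p = vapply(perStudy, function(d) d$p_empirical[t],
                               numeric(1)),
                    n = vapply(studies, function(s) s$selectN, numeric(1)),
                    direction = vapply(perStudy, function(d)
                        sign(d$statistic[t]), numeric(1)),
                    directional = directional)
                Pmeta[r, t] <- cz$p
            }
        })
    }
    rate <- cbind(apply(Pstudy <= alpha, c(2, 3), mean),
                  meta = colMeans(Pmeta <= alpha))
    structure(list(
        rejection = rate,
        se = sqrt(rate * (1 - rate) / replicates),
        alpha = alpha,
        replicates = replicates,
        pvalues = Pmeta,
        pvaluesPerStudy = Pstudy,
        config = studies),
        class = "ExperimentReport")
}

#' @rdname runMetaExperiment
#' @param betaSecondary,fracPositiveSecondary shared secondary-trait
#'   scenario for the three default studies (0 = null).
#' @export
defaultMetaStudies <- function(betaSecondary = 0,
                               fracPositiveSecondary = 1) {
    base <- function(betaPrimary, rho)
        experimentConfig(cohortN = 50000, selectN = 2500,
                         betaPrimary = betaPrimary, rho = rho,
                         betaSecondary = betaSecondary,
                         fracPositiveSecondary = fracPositiveSecondary)
    list(base(-0.5, 0.6), base(0.25, 0.4), base(0, -0.2))
}

#' Quantile-quantile coordinates for p-values
#'
#' @param pvalues vector of p-values (non-empty).
#' @return \code{data.frame} with \code{expected}
#'   (\eqn{(i - 0.5)/n}) and \code{observed} (sorted p-values).
#' @export
qqData <- function(pvalues) {
    n <- length(pvalues)
    if (!n) stop("no p-values supplied")
    data.frame(expected = (seq_len(n) - 0.5) / n,
               observed = sort(pvalues))
}
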