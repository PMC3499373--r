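#' Site-frequency-spectrum configuration
#'
#' Describes how per-site minor-allele frequencies for a simulated region
#' are drawn. The default \code{"reciprocal"} spectrum has density
#' proportional to \eqn{1/x} on \code{[mafMin, mafMax]}, the
#' constant-population neutral infinite-sites shape.
#' \code{"growth"} has density proportional to \eqn{1/x^2}, the
#' strongly rare-shifted shape produced by recent population expansion
#' (and further sharpened by purifying selection), under which most
#' sites sit within a factor of a few of \code{mafMin}.
#' \code{"custom"} samples (with replacement) from a supplied frequency
#' grid, e.g. the output of an external forward simulator.
#'
#' @param nSites number of variant sites (>= 1).
#' @param spectrum \code{"reciprocal"}, \code{"growth"} or
#'   \code{"custom"}.
#' @param mafMin,mafMax frequency bounds, \code{0 < mafMin < mafMax <= 0.5}.
#' @param mafGrid numeric vector of frequencies (required for
#'   \code{"custom"}).
#' @param seed integer seed or \code{NULL}.
#' @return a validated configuration list of class \code{"SfsConfig"}.
#' @export
sfsConfig <- function(nSites, spectrum = c("reciprocal", "growth",
                                           "custom"),
                      mafMin = 2e-5, mafMax = 0.05, mafGrid = NULL,
                      seed = NULL) {
    spectrum <- match.arg(spectrum)
    if (!is.numeric(nSites) || length(nSites) != 1L || nSites < 1 ||
        nSites != round(nSites))
        stop("'nSites' must be a positive integer")
    if (!is.numeric(mafMin) || !is.numeric(mafMax) ||
        !(mafMin > 0 && mafMin < mafMax && mafMax <= 0.5))
        stop("require 0 < mafMin < mafMax <= 0.5")
    if (spectrum == "custom") {
        if (is.null(mafGrid) || !length(mafGrid))
            stop("'custom' spectrum requires a non-empty mafGrid")
        if (any(mafGrid < mafMin | mafGrid > mafMax))
            stop("mafGrid values must lie in [mafMin, mafMax]")
    }
    structure(list(nSites = as.integer(nSites), spectrum = spectrum,
                   mafMin = mafMin, mafMax = mafMax, mafGrid = mafGrid,
                   seed = seed),
              class = "SfsConfig")
}

#' Draw per-site minor-allele frequencies
#'
#' Frequencies are drawn by inverse-CDF sampling: under the reciprocal
#' (\eqn{1/x}) spectrum \eqn{p = a (b/a)^U}, and under the growth
#' (\eqn{1/x^2}) spectrum \eqn{p = 1/(1/a - U(1/a - 1/b))}, with
#' \eqn{U \sim} Uniform(0, 1).
#'
#' @param cfg an \code{\link{sfsConfig}}.
#' @return numeric vector of length \code{nSites} in
#'   \code{[mafMin, mafMax]}.
#' @export
drawSiteFrequencies <- function(cfg) {
    if (!inherits(cfg, "SfsConfig")) stop("'cfg' must be an sfsConfig()")
    withSeed(cfg$seed, {
        switch(cfg$spectrum,
            reciprocal = {
                u <- stats::runif(cfg$nSites)
                cfg$mafMin * (cfg$mafMax / cfg$mafMin)^u
            },
            growth = {
                u <- stats::runif(cfg$nSites)
                1 / (1 / cfg$mafMin -
                     u * (1 / cfg$mafMin - 1 / cfg$mafMax))
            },
            custom = sample(cfg$mafGrid, cfg$nSites, replace = TRUE))
    })
}

#' Assign selection coefficients to sites
#'
#' A stand-in for a population-genetic model with purifying selection:
#' the probability that a site is deleterious (selection coefficient
#' \eqn{s > 10^{-4}}) decreases log-linearly in MAF, from 1 at
#' MAF \eqn{\le 5\times 10^{-5}} to 0 at MAF \eqn{= 3\times 10^{-4}}.
#' The anchors
#' reflect mutation-selection balance (\eqn{q \approx u/s}): variants
#' under appreciable purifying selection are held at very low population
#' frequency, while neutral sites may drift common. Deleterious sites
#' draw
#' \eqn{\log_{10} s \sim} Uniform(-4, -2); others draw
#' \eqn{s \sim} Uniform(0, \eqn{10^{-4}}). Downstream code consumes only
#' the labeling \eqn{s > 10^{-4}} (the causal-eligible pool), so the
#' within-class distributions are inessential.
#'
#' @param mafs vector of minor-allele frequencies in (0, 0.5].
#' @param seed integer seed or \code{NULL}.
#' @return non-negative numeric vector, same length as \code{mafs}.
#' @export
assignSelectionCoeffs <- function(mafs, seed = NULL) {
    if (!length(mafs)) return(numeric(0))
    if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
    withSeed(seed, {
        pDel <- (log10(3e-4) - log10(mafs)) / (log10(3e-4) - log10(5e-5))
        pDel <- pmin(pmax(pDel, 0), 1)
        del <- stats::runif(length(mafs)) < pDel
        s <- stats::runif(length(mafs), 0, 1e-4)
        s[del] <- 10^stats::runif(sum(del), -4, -2)
        s
    })
}

#' Sample Hardy-Weinberg genotypes
#'
#' Entry \eqn{(i, j)} is an independent Binomial(2, \eqn{p_j}) draw
#' (independent sites; no linkage disequilibrium). Implemented per site
#' as a multinomial draw of the genotype-class counts followed by random
#' placement, which is distributionally identical to per-entry draws and
#' fast for rare sites in large cohorts.
#'
#' @param mafs per-site minor-allele frequencies in (0, 0.5].
#' @param n number of individuals (>= 1).
#' @param seed integer seed or \code{NULL}.
#' @param selCoeff optional per-site selection coefficients to carry in
#'   the site table.
#' @param siteIds optional site identifiers.
#' @return a \code{\linkS4class{GenotypeMatrix}} whose \code{maf} column
#'   holds the generating (population) frequencies.
#' @export
sampleGenotypes <- function(mafs, n, seed = NULL, selCoeff = NULL,
                            siteIds = NULL) {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
        stop("'n' must be a positive integer")
    if (!length(mafs)) stop("'mafs' must be non-empty")
    if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
    m <- length(mafs)
    n <- as.integer(n)
    counts <- withSeed(seed, {
        G <- matrix(0L, n, m)
        for (j in seq_len(m)) {
            p <- mafs[j]
            k <- stats::rmultinom(1L, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
            nHom <- k[1L]; nHet <- k[2L]
            if (nHom + nHet > 0L) {
                idx <- sample.int(n, nHom + nHet)
                if (nHom > 0L) G[idx[seq_len(nHom)], j] <- 2L
                if (nHet > 0L) G[idx[nHom + seq_len(nHet)], j] <- 1L
            }
        }
        G
    })
    sites <- data.frame(
        site_id = if (is.null(siteIds)) paste0("s", seq_len(m)) else siteIds,
        maf = mafs,
        sel_coeff = if (is.null(selCoeff)) NA_real_ else selCoeff,
        causal_primary = FALSE,
        causal_secondary = FALSE,
        stringsAsFactors = FALSE)
    colnames(counts) <- sites$site_id
    # invariants hold by construction; skip the full-matrix validity
    # scan, which is costly at cohort scale
    out <- emptyGenotypeMatrix()
    out@counts <- counts
    out@sites <- sites
    out
}

emptyGenotypeMatrix <- function() {
    new("GenotypeMatrix",
        counts = matrix(integer(), 0, 0),
        sites = data.frame(site_id = character(), maf = numeric(),
                           sel_coeff = numeric(),
                           causal_primary = logical(),
                           causal_secondary = logical(),
                           stringsAsFactors = FALSE))
}

#' Simulate a complete rare-variant region
#'
#' Convenience composition: draw frequencies from the spectrum, assign
#' selection coefficients, and sample genotypes for \code{n} individuals.
#'
#' @param cfg an \code{\link{sfsConfig}} (its seed drives all three
#'   stages).
#' @param n number of individuals.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
simulateRegion <- function(cfg, n) {
    withSeed(cfg$seed, {
        mafs <- drawSiteFrequencies(sfsConfig(cfg$nSites, cfg$spectrum,
                                              cfg$mafMin, cfg$mafMax,
                                              cfg$mafGrid, seed = NULL))
        s <- assignSelectionCoeffs(mafs, seed = NULL)
        sampleGenotypes(mafs, n, seed = NULL, selCoeff = s)
    })
}
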