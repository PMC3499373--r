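# Region-based genotype codings and test statistics. All codings
# threshold on the `maf` column of the site table: for genotypes read
# from files this is the sample frequency; simulated data carry their
# generating (population) frequencies. Sites monomorphic in the
# analyzed sample carry no information and never contribute.

# Columns eligible for a coding: annotated MAF at or below the
# threshold and genotype counts actually varying in the sample.
qualifyingSites <- function(G, mafThreshold) {
    maf <- siteInfo(G)$maf
    cnt <- genotypeCounts(G)
    v <- colMeans(cnt^2) - colMeans(cnt)^2
    which(!is.na(maf) & maf <= mafThreshold & v > 0)
}

#' Collapsing (CMC-style) carrier indicator
#'
#' \eqn{x_i = 1} iff individual \eqn{i} carries at least one minor
#' allele at any polymorphic site with annotated MAF at or below the
#' threshold, else 0. This is the rare-variant collapsing arm of CMC;
#' common variants are excluded by the threshold.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param mafThreshold inclusion threshold (default 1\%).
#' @return a \code{\linkS4class{GenotypeCoding}}.
#' @export
codeCMC <- function(G, mafThreshold = 0.01) {
    stopIfNotScalarFraction(mafThreshold, "mafThreshold", openHigh = FALSE)
    j <- qualifyingSites(G, mafThreshold)
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g", mafThreshold))
    x <- as.numeric(rowSums(
        genotypeCounts(G)[, j, drop = FALSE]) > 0)
    new("GenotypeCoding", x = x, weights = numeric(0),
        mafThreshold = mafThreshold, dependsOnTrait = FALSE,
        sites = as.integer(j))
}

#' Weighted-sum (WSS / Madsen-Browning) coding
#'
#' Per-site weights \eqn{w_j = 1/\sqrt{n q_j (1 - q_j)}} with the
#' pseudo-count frequency estimate \eqn{q_j = (c_j + 1)/(2n + 2)}
#' (\eqn{c_j} the minor-allele count over the analyzed sample), so that
#' rarer variants weigh more; \eqn{x_i = \sum_j w_j g_{ij}} over sites
#' with annotated MAF at or below the threshold. The weights do not
#' depend on the trait, as permutation inference requires. Sites that
#' happen to be monomorphic in the sample get a finite weight but
#' contribute zero to every individual.
#'
#' @inheritParams codeCMC
#' @return a \code{\linkS4class{GenotypeCoding}}.
#' @export
codeWSS <- function(G, mafThreshold = 0.01) {
    stopIfNotScalarFraction(mafThreshold, "mafThreshold", openHigh = FALSE)
    n <- nIndividuals(G)
    if (n < 2) stop("need at least 2 individuals")
    maf <- siteInfo(G)$maf
    j <- which(!is.na(maf) & maf <= mafThreshold)  # zero columns allowed
    if (!length(qualifyingSites(G, mafThreshold)))
        stop(sprintf("no polymorphic sites with MAF <= %g", mafThreshold))
    cnt <- genotypeCounts(G)[, j, drop = FALSE]
    cj <- colSums(cnt)
    q <- (cj + 1) / (2 * n + 2)
    w <- 1 / sqrt(n * q * (1 - q))
    new("GenotypeCoding", x = as.vector(cnt %*% w), weights = unname(w),
        mafThreshold = mafThreshold, dependsOnTrait = FALSE,
        sites = as.integer(j))
}

#' Unweighted rare-allele count coding
#'
#' \eqn{x_i =} total minor-allele count over polymorphic sites with
#' annotated MAF at or below the threshold (the per-threshold coding the
#' variable-threshold test maximizes over).
#'
#' @inheritParams codeCMC
#' @return a \code{\linkS4class{GenotypeCoding}}.
#' @export
codeCount <- function(G, mafThreshold = 0.05) {
    stopIfNotScalarFraction(mafThreshold, "mafThreshold", openHigh = FALSE)
    j <- qualifyingSites(G, mafThreshold)
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g", mafThreshold))
    x <- as.vector(rowSums(genotypeCounts(G)[, j, drop = FALSE]))
    new("GenotypeCoding", x = x, weights = numeric(0),
        mafThreshold = mafThreshold, dependsOnTrait = FALSE,
        sites = as.integer(j))
}

#' MAF-binned count codings
#'
#' One unweighted minor-allele count per frequency bin (default: decade
#' bins up to 5\%), over polymorphic sites. Used as a multivariate
#' nuisance coding in the null primary-trait fit: a few frequency
#' strata capture MAF-dependent genetic architecture without fitting a
#' parameter per site.
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param breaks increasing MAF bin boundaries; sites with annotated
#'   MAF in (breaks[k], breaks[k+1]] fall in bin k.
#' @return numeric matrix, one column per non-empty bin.
#' @export
codeMafBins <- function(G, breaks = c(0, 5e-5, 1e-4, 2e-4, 4e-4,
                                       1e-3, 1e-2, 5e-2)) {
    j <- qualifyingSites(G, max(breaks))
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g", max(breaks)))
    maf <- siteInfo(G)$maf[j]
    bin <- cut(maf, breaks)
    cnt <- genotypeCounts(G)[, j, drop = FALSE]
    cols <- lapply(levels(bin)[tabulate(bin, nlevels(bin)) > 0],
                   function(b)
                       rowSums(cnt[, bin == b, drop = FALSE]))
    out <- do.call(cbind, cols)
    colnames(out) <- paste0("mafBin", seq_len(ncol(out)))
    out
}

#' Madsen-Browning weights for a set of sites
#'
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param sites column indices.
#' @return per-site weights \eqn{1/\sqrt{n q_j(1-q_j)}}.
#' @export
madsenBrowningWeights <- function(G, sites) {
    n <- nIndividuals(G)
    cj <- colSums(genotypeCounts(G)[, sites, drop = FALSE])
    q <- (cj + 1) / (2 * n + 2)
    unname(1 / sqrt(n * q * (1 - q)))
}

#' Beta-density MAF weights
#'
#' \eqn{w_j = \mathrm{Beta}(p_j; a, b)} density weights on the empirical
#' MAF, the common SKAT weighting (default Beta(1, 25)).
#'
#' @param maf empirical minor-allele frequencies.
#' @param a,b Beta shape parameters.
#' @return per-site weights.
#' @export
betaMafWeights <- function(maf, a = 1, b = 25) {
    stats::dbeta(maf, a, b)
}

#' Burden score statistic
#'
#' \eqn{U = \sum_i e_i (x_i - \bar x)}: the score statistic is
#' proportional to the sample covariance between the null-model
#' residuals and the genotype coding. Centering the coding makes the
#' statistic invariant to location shifts of \eqn{x}.
#'
#' @param e numeric residual vector (or a \code{\linkS4class{NullFit}}).
#' @param coding a \code{\linkS4class{GenotypeCoding}} or numeric
#'   vector.
#' @return the scalar score U.
#' @export
burdenScore <- function(e, coding) {
    if (is(e, "NullFit")) e <- residuals(e)
    x <- if (is(coding, "GenotypeCoding")) coding@x else coding
    if (length(e) != length(x)) stop("'e' and coding lengths differ")
    if (stats::sd(x) == 0) {
        warning("constant genotype coding: U = 0")
        return(0)
    }
    sum(e * (x - mean(x)))
}

#' Single-variant score
#'
#' The burden score with the coding equal to one site's minor-allele
#' counts.
#'
#' @param e residual vector.
#' @param g minor-allele counts at a single site.
#' @return the scalar score.
#' @export
singleVariantScore <- function(e, g) {
    if (stats::sd(g) == 0)
        stop("site is monomorphic in the analyzed sample")
    burdenScore(e, g)
}

#' Variable-threshold (VT) statistic
#'
#' For every distinct observed MAF \eqn{t} at or below \code{mafCap},
#' form the unweighted count coding over sites with MAF \eqn{\le t},
#' standardize its burden score by the exact permutation SD
#' \eqn{\sqrt{S_e S_x/(n-1)}} (with \eqn{S_e = \sum_i(e_i - \bar e)^2},
#' \eqn{S_x = \sum_i(x_i - \bar x)^2}), and report the maximum absolute
#' standardized score and the threshold attaining it (smallest such
#' threshold on ties).
#'
#' @param e residual vector.
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param mafCap largest threshold considered (default 5\%).
#' @return list with \code{statistic} (\eqn{T_{max}}), \code{threshold},
#'   and the per-threshold table \code{z}.
#' @export
vtStatistic <- function(e, G, mafCap = 0.05) {
    if (is(e, "NullFit")) e <- residuals(e)
    j <- qualifyingSites(G, mafCap)
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g: ", mafCap),
             "VT has no candidate thresholds")
    f <- siteInfo(G)$maf[j]
    ord <- order(f)
    cnt <- genotypeCounts(G)[, j[ord], drop = FALSE]
    fSorted <- f[ord]
    thr <- unique(fSorted)
    # cumulative per-individual counts at each distinct threshold
    mj <- ncol(cnt)
    Ltri <- matrix(0, mj, mj)
    Ltri[upper.tri(Ltri, diag = TRUE)] <- 1
    keep <- !duplicated(fSorted, fromLast = TRUE)
    X <- (cnt %*% Ltri)[, keep, drop = FALSE]
    eC <- e - mean(e)
    Se <- sum(eC^2)
    n <- length(e)
    xBar <- colMeans(X)
    Sx <- colSums(X^2) - n * xBar^2
    U <- as.vector(crossprod(eC, X))     # centering of X immaterial: e centered
    z <- U / sqrt(Se * Sx / (n - 1))
    iMax <- which.max(abs(z))
    list(statistic = unname(abs(z)[iMax]), threshold = unname(thr[iMax]),
         z = data.frame(threshold = thr, z = z))
}

#' Kernel variance-component (SKAT-type) statistic
#'
#' The quadratic form \eqn{Q = e' K e} with the weighted linear kernel
#' \eqn{K = G W G'}, computed in the fast form
#' \eqn{Q = \sum_j w_j (e' g_j)^2} over polymorphic sites with empirical
#' MAF at or below the threshold. \eqn{e} are the deviations of the
#' secondary trait from its null-model mean.
#'
#' @param e residual vector.
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param weights \code{"madsen-browning"} (default), \code{"beta"}
#'   (Beta(1,25) on MAF), \code{"none"}, or a numeric vector with one
#'   weight per qualifying site.
#' @param mafThreshold inclusion threshold (default 1\%).
#' @return the scalar statistic Q.
#' @export
skatStatistic <- function(e, G, weights = "madsen-browning",
                          mafThreshold = 0.01) {
    if (is(e, "NullFit")) e <- residuals(e)
    j <- qualifyingSites(G, mafThreshold)
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g", mafThreshold))
    w <- resolveSkatWeights(G, j, weights)
    cnt <- genotypeCounts(G)[, j, drop = FALSE]
    sum(w * as.vector(crossprod(e, cnt))^2)
}

resolveSkatWeights <- function(G, sites, weights) {
    if (is.numeric(weights)) {
        if (length(weights) != length(sites))
            stop("need one weight per qualifying site")
        return(weights)
    }
    switch(match.arg(weights, c("madsen-browning", "beta", "none")),
           "madsen-browning" = madsenBrowningWeights(G, sites),
           "beta" = betaMafWeights(siteInfo(G)$maf[sites]),
           "none" = rep(1, length(sites)))
}

#' Adaptive-cluster (KBAC-type) statistic for quantitative traits
#'
#' Individuals are grouped by their distinct multi-site genotype over
#' qualifying rare sites; the all-zero genotype is the reference group.
#' Each carrier group \eqn{k} (size \eqn{n_k}, mean residual
#' \eqn{\bar e_k}) receives the adaptive weight
#' \eqn{w_k = \Phi(\bar e_k \sqrt{n_k} / \hat\sigma)} -- the estimated
#' probability that the genotype raises the trait -- and the statistic is
#' \eqn{T = \sum_{k \ne 0} w_k n_k \bar e_k}. The weights depend on the
#' residuals, so they are recomputed inside every permutation.
#'
#' @param e residual vector.
#' @param G a \code{\linkS4class{GenotypeMatrix}}.
#' @param mafThreshold inclusion threshold (default 1\%).
#' @param sigma residual SD used in the weight; defaults to
#'   \code{sd(e)}.
#' @return the scalar statistic T (signed; tests use |T|).
#' @export
kbacStatistic <- function(e, G, mafThreshold = 0.01, sigma = NULL) {
    if (is(e, "NullFit")) e <- residuals(e)
    grp <- kbacGroups(G, mafThreshold)
    kbacFromGroups(e, grp, sigma)
}

# Genotype-pattern grouping reused across permutations: group 0 is the
# all-zero (reference) pattern.
kbacGroups <- function(G, mafThreshold = 0.01) {
    j <- qualifyingSites(G, mafThreshold)
    if (!length(j))
        stop(sprintf("no polymorphic sites with MAF <= %g", mafThreshold))
    cnt <- genotypeCounts(G)[, j, drop = FALSE]
    # pattern keys built over carriers only; the all-zero pattern is the
    # reference group
    carrier <- rowSums(cnt) > 0L
    key <- rep("", nrow(cnt))
    if (any(carrier))
        key[carrier] <- do.call(
            paste, c(as.data.frame(cnt[carrier, , drop = FALSE]),
                     sep = ","))
    uk <- unique(key)
    id <- match(key, uk)
    list(id = id, nGroups = length(uk),
         refGroup = match("", uk),         # NA if every individual carries
         sizes = tabulate(id, length(uk)))
}

kbacFromGroups <- function(e, grp, sigma = NULL) {
    if (is.null(sigma)) sigma <- stats::sd(e)
    if (grp$nGroups == 1L) {
        warning("all individuals share one genotype pattern: T = 0")
        return(0)
    }
    sums <- as.vector(rowsum(e, grp$id))
    means <- sums / grp$sizes
    w <- stats::pnorm(means * sqrt(grp$sizes) / sigma)
    keep <- seq_len(grp$nGroups)
    if (!is.na(grp$refGroup)) keep <- keep[-grp$refGroup]
    sum(w[keep] * grp$sizes[keep] * means[keep])
}
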