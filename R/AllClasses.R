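#' @import methods
NULL

#' Rare-variant genotype matrix
#'
#' Individuals-by-sites minor-allele count matrix with per-site
#' annotations. Counts are 0/1/2 minor-allele dosages; sites are oriented
#' to the minor allele at construction time and never re-oriented.
#'
#' @slot counts integer matrix, individuals in rows, sites in columns,
#'   entries in \{0, 1, 2\}.
#' @slot sites \code{data.frame} with one row per site and columns
#'   \code{site_id} (character), \code{maf} (fraction in (0, 0.5]),
#'   \code{sel_coeff} (non-negative selection coefficient, may be
#'   \code{NA}), \code{causal_primary}, \code{causal_secondary}
#'   (logical flags, set only by \code{\link{selectCausalSets}}).
#'
#' @seealso \code{\link{sampleGenotypes}}, \code{\link{readGenotypesTsv}},
#'   \code{\link{readGenotypesVcf}}
#' @export
setClass("GenotypeMatrix",
    representation(counts = "matrix", sites = "data.frame"),
    validity = function(object) {
        msg <- character()
        cn <- object@counts
        if (!is.integer(cn))
            msg <- c(msg, "counts must be an integer matrix")
        else if (length(cn) && (min(cn) < 0L || max(cn) > 2L))
            msg <- c(msg, "genotype counts must lie in {0, 1, 2}")
        need <- c("site_id", "maf", "sel_coeff",
                  "causal_primary", "causal_secondary")
        if (!all(need %in% names(object@sites)))
            msg <- c(msg, paste("sites must have columns:",
                                paste(need, collapse = ", ")))
        else {
            if (nrow(object@sites) != ncol(cn))
                msg <- c(msg, "one sites row required per counts column")
            maf <- object@sites$maf
            if (any(!is.na(maf) & (maf <= 0 | maf > 0.5)))
                msg <- c(msg, "site maf must lie in (0, 0.5]")
            sc <- object@sites$sel_coeff
            if (any(!is.na(sc) & sc < 0))
                msg <- c(msg, "sel_coeff must be non-negative")
        }
        if (length(msg)) msg else TRUE
    })

#' Two-sided tail selection region
#'
#' The primary-trait region defining ascertainment: an individual is
#' selected iff \eqn{y_1 \le} \code{lowerCut} or \eqn{y_1 \ge}
#' \code{upperCut}.
#'
#' @slot lowerCut upper bound of the lower tail.
#' @slot upperCut lower bound of the upper tail; must exceed
#'   \code{lowerCut}.
#' @export
setClass("SelectionRegion",
    representation(lowerCut = "numeric", upperCut = "numeric"),
    validity = function(object) {
        if (length(object@lowerCut) != 1L || length(object@upperCut) != 1L)
            return("cuts must be scalars")
        if (is.na(object@lowerCut) || is.na(object@upperCut))
            return("cuts must not be NA")
        if (!(object@lowerCut < object@upperCut))
            return("lowerCut must be strictly below upperCut")
        TRUE
    })

#' Extreme-tail ascertained sample
#'
#' @slot indices cohort positions of the selected individuals (ascending).
#' @slot A logical ascertainment indicator over the whole cohort.
#' @slot region the \code{\linkS4class{SelectionRegion}} used.
#' @slot tail per-selected-individual label, \code{"low"} or \code{"high"}.
#' @export
setClass("AscertainedSample",
    representation(indices = "integer", A = "logical",
                   region = "SelectionRegion", tail = "character"),
    validity = function(object) {
        msg <- character()
        if (!identical(which(object@A), object@indices))
            msg <- c(msg, "A must be TRUE exactly at 'indices'")
        if (length(object@tail) != length(object@indices))
            msg <- c(msg, "one tail label per selected individual")
        if (length(object@tail) && !all(object@tail %in% c("low", "high")))
            msg <- c(msg, "tail labels must be 'low' or 'high'")
        if (length(msg)) msg else TRUE
    })

#' Ascertainment-corrected null-model fit
#'
#' Nuisance-parameter estimates from the factorized null fit: the
#' two-sided truncated-normal model for the primary trait, then ordinary
#' least squares for the secondary trait conditional on the primary-trait
#' residual. The residual vector is the package's interoperability
#' surface: approximately normal and exchangeable under the null, it can
#' be fed to any rare-variant test.
#'
#' @slot gamma1 primary-trait covariate coefficients (incl. intercept).
#' @slot betaP primary-trait effect on the supplied genotype coding
#'   (\code{NA} if the coding was degenerate and dropped).
#' @slot sigma1 primary residual SD.
#' @slot gamma2 secondary-trait covariate coefficients (incl. intercept).
#' @slot tau coefficient of the primary-trait residual in the secondary
#'   conditional mean; consistent for \eqn{\rho\sigma_2/\sigma_1}.
#' @slot sigmaCond conditional residual SD of y2 given y1.
#' @slot converged optimizer convergence flag.
#' @slot loglik maximized truncated-normal log-likelihood.
#' @slot residuals exchangeable secondary-trait residuals.
#' @export
setClass("NullFit",
    representation(gamma1 = "numeric", betaP = "numeric", sigma1 = "numeric",
                   gamma2 = "numeric", tau = "numeric", sigmaCond = "numeric",
                   converged = "logical", loglik = "numeric",
                   residuals = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@sigma1) && !is.na(object@sigma1) &&
            object@sigma1 <= 0)
            msg <- c(msg, "sigma1 must be positive")
        if (length(object@sigmaCond) && !is.na(object@sigmaCond) &&
            object@sigmaCond <= 0)
            msg <- c(msg, "sigmaCond must be positive")
        if (length(msg)) msg else TRUE
    })

#' Per-individual genotype coding for a region
#'
#' A scalar coding \eqn{X(G_i)} per individual, plus the per-site weights
#' and MAF threshold that produced it. Only polymorphic sites with
#' empirical MAF at or below the threshold contribute.
#'
#' @slot x numeric per-individual coding.
#' @slot weights per-contributing-site weights (length 0 for unweighted
#'   codings).
#' @slot mafThreshold MAF inclusion threshold used.
#' @slot dependsOnTrait whether the coding used trait values (adaptive
#'   codings must be recomputed inside permutations).
#' @slot sites column indices of the contributing sites.
#' @export
setClass("GenotypeCoding",
    representation(x = "numeric", weights = "numeric",
                   mafThreshold = "numeric", dependsOnTrait = "logical",
                   sites = "integer"))

#' Region-test result
#'
#' @slot test test name.
#' @slot statistic observed statistic (score U or quadratic form Q).
#' @slot pEmpirical permutation p-value (add-one convention).
#' @slot pAnalytic analytic p-value when available, else \code{NA}.
#' @slot nPerm number of permutations used.
#' @slot vtThreshold selected MAF threshold (VT only, else \code{NA}).
#' @export
setClass("TestResult",
    representation(test = "character", statistic = "numeric",
                   pEmpirical = "numeric", pAnalytic = "numeric",
                   nPerm = "integer", vtThreshold = "numeric"),
    validity = function(object) {
        p <- object@pEmpirical
        if (length(p) && !is.na(p) && (p <= 0 || p > 1))
            return("pEmpirical must lie in (0, 1]")
        TRUE
    })
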