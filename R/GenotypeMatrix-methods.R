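#' Construct a GenotypeMatrix
#'
#' @param counts integer matrix of minor-allele counts (individuals x
#'   sites), entries in \{0, 1, 2\}.
#' @param sites optional site annotation \code{data.frame}; defaults are
#'   filled in (\code{site_id = "s1", ...}, empirical MAF, \code{NA}
#'   selection coefficients, all-\code{FALSE} causal flags). Monomorphic
#'   columns get \code{maf = NA}: permitted before filtering, excluded
#'   from every test coding.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
GenotypeMatrix <- function(counts, sites = NULL) {
    counts <- as.matrix(counts)
    if (!is.integer(counts)) {
        if (any(counts != round(counts)))
            stop("genotype counts must be integers")
        storage.mode(counts) <- "integer"
    }
    m <- ncol(counts)
    if (is.null(sites)) {
        maf <- empiricalMafFromCounts(counts)
        maf[maf == 0] <- NA_real_
        sites <- data.frame(
            site_id = if (!is.null(colnames(counts))) colnames(counts)
                      else paste0("s", seq_len(m)),
            maf = maf,
            sel_coeff = NA_real_,
            causal_primary = FALSE,
            causal_secondary = FALSE,
            stringsAsFactors = FALSE)
    }
    colnames(counts) <- sites$site_id
    new("GenotypeMatrix", counts = counts, sites = sites)
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypeCounts", "GenotypeMatrix", function(x) x@counts)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("siteInfo", "GenotypeMatrix", function(x) x@sites)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) nrow(x@counts))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) ncol(x@counts))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("empiricalMaf", "GenotypeMatrix",
          function(x) empiricalMafFromCounts(x@counts))

#' @rdname GenotypeMatrix-class
#' @param i,j,drop row (individual) and column (site) subsets.
#' @param ... ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@counts))
    if (missing(j)) j <- seq_len(ncol(x@counts))
    new("GenotypeMatrix", counts = x@counts[i, j, drop = FALSE],
        sites = x@sites[j, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
    maf <- object@sites$maf
    cat("GenotypeMatrix:", nrow(object@counts), "individuals x",
        ncol(object@counts), "sites\n")
    if (length(maf))
        cat("  site MAF range:",
            format(suppressWarnings(min(maf, na.rm = TRUE)), digits = 3), "-",
            format(suppressWarnings(max(maf, na.rm = TRUE)), digits = 3),
            sprintf(" (%d monomorphic)\n", sum(is.na(maf))))
    cat("  causal primary/secondary:",
        sum(object@sites$causal_primary), "/",
        sum(object@sites$causal_secondary), "sites\n")
})

#' @rdname SelectionRegion-class
#' @param lowerCut,upperCut tail cut points (\code{lowerCut < upperCut}).
#' @export
SelectionRegion <- function(lowerCut, upperCut) {
    new("SelectionRegion", lowerCut = as.numeric(lowerCut),
        upperCut = as.numeric(upperCut))
}

#' @rdname SelectionRegion-class
#' @export
setMethod("inRegion", "SelectionRegion", function(region, y) {
    y <= region@lowerCut | y >= region@upperCut
})

setMethod("show", "SelectionRegion", function(object) {
    cat(sprintf("SelectionRegion: y1 <= %g  or  y1 >= %g\n",
                object@lowerCut, object@upperCut))
})

setMethod("show", "AscertainedSample", function(object) {
    cat("AscertainedSample:", length(object@indices), "of",
        length(object@A), "individuals",
        sprintf("(%d low / %d high tail)\n",
                sum(object@tail == "low"), sum(object@tail == "high")))
    show(object@region)
})

setMethod("show", "NullFit", function(object) {
    cat("Ascertainment-corrected null fit\n")
    cat(sprintf("  primary:   beta_p = (%s), sigma1 = %.4g%s\n",
                paste(format(object@betaP, digits = 3, trim = TRUE),
                      collapse = ", "),
                object@sigma1,
                if (isTRUE(object@converged)) "" else "  [NOT converged]"))
    cat(sprintf("  secondary: tau = %.4g, sigma2|1 = %.4g\n",
                object@tau, object@sigmaCond))
    cat(sprintf("  loglik = %.4g, %d residuals\n",
                object@loglik, length(object@residuals)))
})

#' @rdname NullFit-class
#' @param object a \code{NullFit}.
#' @param ... ignored.
#' @return the exchangeable secondary-trait residuals.
#' @export
setMethod("residuals", "NullFit", function(object, ...) object@residuals)

setMethod("show", "TestResult", function(object) {
    cat(sprintf("%s: statistic = %.4g, empirical p = %.4g (%d permutations)",
                object@test, object@statistic, object@pEmpirical,
                object@nPerm))
    if (!is.na(object@pAnalytic))
        cat(sprintf(", analytic p = %.4g", object@pAnalytic))
    if (!is.na(object@vtThreshold))
        cat(sprintf(", MAF threshold = %.4g", object@vtThreshold))
    cat("\n")
})

#' @rdname TestResult-class
#' @export
setMethod("pValue", "TestResult", function(x) x@pEmpirical)
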