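#' Select individuals with extreme primary-trait values
#'
#' Rank-based two-tail selection: the \code{ceiling(nSelect/2)} smallest
#' and \code{floor(nSelect/2)} largest primary-trait values are taken
#' (the extra individual of an odd \code{nSelect} goes to the lower
#' tail). Ties at a cut are broken by original index, so the selection is
#' deterministic and reproducible. The stored region cuts are the
#' innermost selected value of each tail.
#'
#' @param y1 cohort primary-trait vector.
#' @param nSelect number to select (2 <= nSelect <= length(y1)).
#' @return an \code{\linkS4class{AscertainedSample}}.
#' @export
selectExtremes <- function(y1, nSelect) {
    n <- length(y1)
    if (!is.numeric(nSelect) || length(nSelect) != 1L ||
        nSelect != round(nSelect) || nSelect < 2)
        stop("'nSelect' must be an integer >= 2")
    if (nSelect > n)
        stop(sprintf("cannot select %d individuals from a cohort of %d",
                     nSelect, n))
    nLow <- ceiling(nSelect / 2)
    nHigh <- nSelect - nLow
    ord <- order(y1, seq_len(n))          # stable: ties by original index
    low <- ord[seq_len(nLow)]
    high <- ord[seq.int(n - nHigh + 1L, n)]
    lowerCut <- y1[low[nLow]]
    upperCut <- y1[high[1L]]
    if (!(lowerCut < upperCut))
        stop("degenerate selection region: tail cuts coincide (ties span ",
             "the whole unselected range)")
    idx <- sort(c(low, high))
    A <- logical(n)
    A[idx] <- TRUE
    new("AscertainedSample",
        indices = as.integer(idx), A = A,
        region = SelectionRegion(lowerCut, upperCut),
        tail = ifelse(y1[idx] <= lowerCut, "low", "high"))
}

#' Selection region from empirical quantiles
#'
#' Cuts at the empirical \code{qLow} and \code{qHigh} quantiles of the
#' cohort primary trait; an individual is ascertained iff its value lies
#' at or below the lower cut or at or above the upper cut. Use when the
#' design is specified as tail fractions (e.g. upper and lower 5\%)
#' rather than a target sample size.
#'
#' @param y1 cohort primary-trait vector.
#' @param qLow,qHigh tail quantiles, \code{0 < qLow < qHigh < 1}.
#' @return a \code{\linkS4class{SelectionRegion}}.
#' @export
regionFromQuantiles <- function(y1, qLow, qHigh) {
    stopIfNotScalarFraction(qLow, "qLow")
    stopIfNotScalarFraction(qHigh, "qHigh")
    if (!(qLow < qHigh)) stop("'qLow' must be below 'qHigh'")
    cuts <- stats::quantile(y1, c(qLow, qHigh), names = FALSE, na.rm = FALSE)
    if (!(cuts[1] < cuts[2]))
        stop("degenerate region: the two quantiles coincide")
    SelectionRegion(cuts[1], cuts[2])
}

#' Ascertain a sample from a known region
#'
#' @param y1 cohort primary-trait vector.
#' @param region a \code{\linkS4class{SelectionRegion}} (e.g. known
#'   design cuts, overriding empirical ones).
#' @return an \code{\linkS4class{AscertainedSample}}.
#' @export
ascertainByRegion <- function(y1, region) {
    A <- inRegion(region, y1)
    idx <- which(A)
    if (!length(idx)) stop("no individuals fall in the selection region")
    new("AscertainedSample", indices = as.integer(idx), A = A,
        region = region,
        tail = ifelse(y1[idx] <= region@lowerCut, "low", "high"))
}
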