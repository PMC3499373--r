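# Sample-size weighted Z-score (Stouffer) meta-analysis across cohorts
# ascertained on different primary traits.

MIN_P <- 1e-15

#' Transform a per-study p-value to a Z score
#'
#' Directional statistics (burden-type scores with a sign) use
#' \eqn{Z = d\,\Phi^{-1}(1 - p/2)} with \eqn{d} the direction of effect;
#' direction-free statistics (quadratic forms, maxima) use the one-sided
#' transform \eqn{Z = \Phi^{-1}(1 - p)}. p-values are clamped into
#' \code{[1e-15, 1 - 1e-15]} before the quantile transform (with a
#' warning at the p = 1 boundary); p = 0 is rejected -- impossible under
#' the add-one permutation convention.
#'
#' @param p p-value in (0, 1].
#' @param direction effect sign in \{-1, 0, +1\} (ignored when
#'   \code{directional = FALSE}).
#' @param directional whether the source statistic carries a sign.
#' @return the Z score.
#' @export
pToZ <- function(p, direction = 0, directional = TRUE) {
    if (any(p <= 0))
        stop("p-values must be positive (add-one permutation p never is 0)")
    if (any(p > 1)) stop("p-values must not exceed 1")
    atBoundary <- (!directional & p >= 1 - MIN_P)
    if (any(atBoundary))
        warning("p at the upper boundary: Z clamped")
    p <- pmin(pmax(p, MIN_P), 1 - MIN_P)
    if (directional) {
        if (!all(direction %in% c(-1, 0, 1)))
            stop("'direction' entries must be in {-1, 0, +1}")
        direction * stats::qnorm(1 - p / 2)
    } else {
        stats::qnorm(1 - p)
    }
}

#' Combine studies by sqrt-n weighted Z
#'
#' \deqn{Z_{meta} = \frac{\sum_i \sqrt{n_i} Z_i}{\sqrt{\sum_i n_i}},}
#' with per-study Z from \code{\link{pToZ}}. The meta p-value is
#' two-sided for directional statistics and upper-tail for
#' direction-free ones.
#'
#' @param p per-study p-values.
#' @param n per-study effective sample sizes.
#' @param direction per-study effect signs (directional case).
#' @param directional whether the underlying statistic is signed.
#' @return list with \code{z} (\eqn{Z_{meta}}) and \code{p}.
#' @export
combineZ <- function(p, n, direction = rep(0, length(p)),
                     directional = TRUE) {
    if (!length(p)) stop("need at least one study")
    if (length(n) != length(p)) stop("'p' and 'n' lengths differ")
    if (any(n < 1)) stop("sample sizes must be >= 1")
    z <- pToZ(p, direction, directional)
    zMeta <- sum(sqrt(n) * z) / sqrt(sum(n))
    pMeta <- if (directional) 2 * stats::pnorm(-abs(zMeta))
             else stats::pnorm(zMeta, lower.tail = FALSE)
    list(z = zMeta, p = min(pMeta, 1))
}

#' Meta-analyze a table of per-study test results
#'
#' Burden-type tests (\code{cmc}, \code{wss}, \code{single}) enter
#' directionally with the sign of their score; \code{vt}, \code{skat}
#' and \code{kbac} enter direction-free via the one-sided transform.
#'
#' @param results \code{data.frame} with columns \code{study_id},
#'   \code{test}, \code{p}, \code{direction}, \code{n}.
#' @return \code{data.frame} with one row per test: \code{test},
#'   \code{z_meta}, \code{p_meta}, \code{n_studies}.
#' @export
metaAnalyze <- function(results) {
    need <- c("study_id", "test", "p", "direction", "n")
    if (!all(need %in% names(results)))
        stop("results must have columns: ", paste(need, collapse = ", "))
    directionalTests <- c("cmc", "wss", "single")
    out <- lapply(split(results, results$test), function(d) {
        directional <- d$test[1] %in% directionalTests
        cz <- combineZ(d$p, d$n, d$direction, directional)
        data.frame(test = d$test[1], z_meta = cz$z, p_meta = cz$p,
                   n_studies = nrow(d))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
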