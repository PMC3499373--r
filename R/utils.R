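# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. `seed = NULL` leaves the
# RNG stream untouched (draws advance it as usual).
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number or NULL")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# log(exp(a) + exp(b)), vectorized, tolerant of -Inf.
logspaceAdd <- function(a, b) {
    m <- pmax(a, b)
    out <- m + log1p(exp(pmin(a, b) - m))
    out[is.infinite(m) & m < 0] <- -Inf
    out
}

# Column minor-allele frequencies as stored (no re-orientation): mean
# minor-allele count over 2. Used by all codings.
empiricalMafFromCounts <- function(counts) {
    colMeans(counts) / 2
}

stopIfNotScalarFraction <- function(x, name, openLow = TRUE, openHigh = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name))
    lowOk <- if (openLow) x > 0 else x >= 0
    highOk <- if (openHigh) x < 1 else x <= 1
    if (!lowOk || !highOk)
        stop(sprintf("'%s' = %g is outside the admissible range", name, x))
    invisible(TRUE)
}
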