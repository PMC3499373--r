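# Small fixtures built in code.

# A tiny genotype matrix with fully controlled counts and site table.
toyGenotypes <- function(counts, maf = NULL, selCoeff = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    m <- ncol(counts)
    if (is.null(maf)) {
        maf <- colMeans(counts) / 2
        maf[maf == 0] <- NA_real_
    }
    sites <- data.frame(
        site_id = paste0("s", seq_len(m)),
        maf = maf,
        sel_coeff = if (is.null(selCoeff)) NA_real_ else selCoeff,
        causal_primary = FALSE,
        causal_secondary = FALSE,
        stringsAsFactors = FALSE)
    GenotypeMatrix(counts, sites)
}

# A random sparse rare-variant matrix for property tests.
randomRareGenotypes <- function(n, m, maf = 0.05, seed = 1) {
    withr::with_seed(seed,
        toyGenotypes(matrix(rbinom(n * m, 2, maf), n, m)))
}
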