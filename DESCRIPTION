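Package: extremeRV
Title: Secondary-Trait Rare-Variant Association Testing under
    Extreme-Phenotype Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unbiased region-based association testing of secondary
    quantitative traits with rare variants in samples ascertained on
    extreme values of a primary trait. Fits an ascertainment-corrected
    null model (two-sided truncated-normal likelihood for the primary
    trait, conditional least squares for the secondary trait), yielding
    exchangeable secondary-trait residuals that license standard
    permutation inference for collapsing (CMC), weighted-sum (WSS),
    variable-threshold (VT), kernel variance-component (SKAT) and
    adaptive-cluster (KBAC) tests. Includes sample-size weighted Z-score
    meta-analysis across differently ascertained cohorts, a
    site-frequency-spectrum driven rare-variant genotype simulator, a
    bivariate-normal trait simulator, and a harness for type-I-error and
    power experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
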