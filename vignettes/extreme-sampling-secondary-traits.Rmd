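---
title: "Secondary-trait rare-variant association under extreme-phenotype sampling"
author: "extremeRV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary-trait rare-variant association under extreme-phenotype sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremeRV)
```

## The problem

Sequencing studies often select individuals with extreme values of one
quantitative trait (the *primary* trait: say, LDL cholesterol) because
extreme-tail sampling enriches for rare functional alleles. The same
samples usually carry many other measured phenotypes (*secondary*
traits: blood pressure, triglycerides, ...), and it is tempting to test
those for rare-variant association "for free". The temptation is a
trap: selection on the primary trait distorts the joint distribution of
genotypes and any trait correlated with it. If a gene affects the
primary trait (per-coding effect $\beta_p \neq 0$) and the residuals of
the two traits are correlated ($\rho \neq 0$), naive regression of the
secondary trait on genotype is biased even when the gene has no
secondary-trait effect at all, and type-I error is inflated. The bias
grows linearly in $\rho$ and, for moderate effects, approximately
linearly in $\beta_p$; stratifying by tail or adding a tail indicator
as a covariate reduces but does not remove it (`naiveBias()` evaluates
all three variants).

## The model and the correction

Write $y_{1i}$, $y_{2i}$ for the two traits, $X_i$ for covariates,
$G_i$ for the multi-site rare-variant genotype in the region, and
$x_i = X(G_i)$ for a scalar region coding (carrier indicator, weighted
sum, ...). The null model (no secondary-trait association) is a
bivariate linear model

$$
y_{1i} = X_{1i}\gamma_1 + \beta_p x_i + \epsilon_{1i},\qquad
y_{2i} = X_{2i}\gamma_2 + \epsilon_{2i},
$$

with $(\epsilon_1, \epsilon_2)$ bivariate normal, SDs
$(\sigma_1, \sigma_2)$, correlation $\rho$. An individual enters the
sample iff $y_1$ falls in a two-sided tail region
$\{y_1 \le l\} \cup \{y_1 \ge u\}$ (ascertainment indicator $A$).

The likelihood for the selected sample factorizes: the ascertainment
affects the marginal law of $y_1$ (a two-sided-truncated normal), while
the law of $y_2$ *given* $y_1$ is untouched, because selection acts
only through $y_1$. The package therefore fits the null model in two
stages (`computeResiduals()`):

1. **Truncated primary fit** (`fitTruncatedPrimary()`): maximize
   $\prod_i \phi((y_{1i}-\mu_i)/\sigma_1)\big/
   [\Phi(\tfrac{l-\mu_i}{\sigma_1}) + 1 - \Phi(\tfrac{u-\mu_i}{\sigma_1})]$
   over $(\gamma_1, \beta_p, \log\sigma_1)$, with
   $\mu_i = X_{1i}\gamma_1 + \beta_p x_i$. BFGS with an analytic
   gradient, OLS starting values, a Nelder-Mead restart on flagged
   non-convergence, and complementary-CDF log-space evaluation of the
   ascertainment probability to avoid cancellation at extreme cuts.
2. **Conditional secondary fit** (`fitConditionalSecondary()`): OLS of
   $y_2$ on an intercept, $X_2$, and the primary residual
   $y_1 - \hat\mu_1$. The residual coefficient $\hat\tau$ is consistent
   for $\rho\sigma_2/\sigma_1$; the fit residuals
   $\hat e_i$ are, by Slutsky's theorem, approximately normal and
   exchangeable under the null.

Those residuals are the package's interoperability surface: any
rare-variant statistic computed on $(\hat e, G)$ can be calibrated by
permuting $\hat e$.

## Tests and inference

Five region statistics are built in (`regionTests()`), all functions of
the residuals and the genotype coding:

* **CMC** — carrier indicator over sites with MAF $\le$ 1%;
* **WSS** — Madsen–Browning weighted sum,
  $w_j = 1/\sqrt{n q_j(1-q_j)}$ with pseudo-count allele frequency;
* **VT** — the burden z-score maximized over every observed MAF
  threshold up to 5%, standardized by the exact permutation variance
  $S_e S_x/(n-1)$;
* **SKAT** — the weighted linear-kernel quadratic form
  $Q = \sum_j w_j (e^\top g_j)^2$, with an analytic
  mixture-of-chi-squares tail (Imhof inversion, Liu–Tang–Zhang
  fallback) alongside the permutation p-value;
* **KBAC** — individuals grouped by distinct multi-site genotype;
  carrier group $k$ gets the adaptive weight
  $w_k = \Phi(\bar e_k \sqrt{n_k}/\hat\sigma)$ and
  $T = \sum_k w_k n_k \bar e_k$, with the weights recomputed inside
  every permutation. The binary-trait original uses hypergeometric
  enrichment probabilities; this quantitative-trait transplant replaces
  them with Gaussian tail probabilities and is a reconstruction, not a
  port of a published formula — treat cross-implementation comparisons
  accordingly.

Empirical p-values use the add-one convention
$p = (1 + \#\{|T_b| \ge |T_{obs}|\})/(B+1)$: valid, never zero, minimum
$1/(B+1)$. Burden-type scores are two-sided; VT and SKAT, being maxima
and quadratic forms, use the upper tail. KBAC's statistic is signed, so
it is compared by absolute value — a one-sided version would be blind
to trait-lowering genes, which real data contain. Batched permutation
reuses one residual-by-genotype cross-product for every linear
statistic; KBAC recomputes adaptive weights per permutation from
precomputed genotype groups.

Meta-analysis (`combineZ()`, `metaAnalyze()`) combines per-study
p-values by sample-size-weighted Z:
$Z_{meta} = \sum_i \sqrt{n_i} Z_i / \sqrt{\sum_i n_i}$. Signed tests
enter via $Z = d\,\Phi^{-1}(1 - p/2)$ with direction
$d = \mathrm{sign}(U)$; direction-free tests via
$\Phi^{-1}(1-p)$ with an upper-tail meta p. p-values are clamped at
$10^{-15}$ before the quantile transform.

## The synthetic cohort generator

No external data ship with the package; the simulation engine
(`simulateRegion()`, `simulateTraits()`, `selectExtremes()`) emulates
the study conditions of a sequencing design that selects 5,000 trait
extremes from a cohort of 100,000.

* **Site frequencies** follow a growth-skewed ($1/x^2$) spectrum on
  $[2\times 10^{-5}, 0.05]$. Recent population expansion — a defining
  feature of human demographic history, further sharpened by purifying
  selection — places the overwhelming majority of segregating sites
  within a factor of a few of the rare boundary, with a thin common
  tail. The constant-population neutral shape ($1/x$,
  `spectrum = "reciprocal"`) and an arbitrary external frequency table
  (`spectrum = "custom"`) are also available; the $1/x$ shape puts far
  more mass at 0.1–1% than a post-expansion gene region carries, which
  simultaneously dilutes region tests with neutral carriers and
  stresses the null model (see the nuisance section).
* **Purifying selection**: the probability that a site is deleterious
  ($s > 10^{-4}$) declines log-linearly from 1 at MAF $5\times10^{-5}$
  to 0 at MAF $3\times10^{-4}$. This encodes mutation–selection balance
  ($q \approx u/s$, so $s > 10^{-4}$ with per-site mutation rates near
  $10^{-8}$ pins equilibrium frequencies at or below $\sim10^{-4}$):
  variants under appreciable selection cannot drift common, and the
  causal-eligible pool consists of sites that are near-singletons even
  in a selected sample of thousands. Earlier drafts of the generator
  let selected variants reach percent (then tenth-of-a-percent)
  frequencies; that is biologically inconsistent and, notably, breaks
  the exchangeability of null-model residuals — no coarse nuisance
  coding can absorb sizeable per-site primary-trait signals, and
  threshold-scanning or quadratic statistics detect the leftovers.
* **Causal architecture**: among deleterious sites, 50% are drawn as
  causal for the primary trait and, independently, 50% for the
  secondary trait; the intersection is pleiotropic. Effect magnitudes
  are constant ($|\beta_j| = c_1$) or MAF-dependent
  ($|\beta_j| = c_1 + c_2|\log_{10} p_j|$); a configurable fraction of
  effects is positive (1 for unidirectional, 0.8 for the 80/20
  bidirectional scenario).
* **Region size** defaults to 200 sites per gene region
  (`experimentConfig(nSites = ...)`). Together with the spectrum and
  the balance constraint this puts the aggregate causal carrier
  frequency near 0.5–1% spread over near-singleton sites — the
  operating regime in which extreme-sampling designs are interesting:
  mid-range power at per-allele effects of 0.25–0.5 trait SD, serious
  naive-analysis inflation, and calibrated corrected tests. Far fewer
  sites collapse every experiment into a low-power, low-bias corner;
  concentrating the same carrier mass on a few higher-frequency sites
  instead violates mutation–selection balance and the null model's
  exchangeability (above).
* **Traits** follow the bivariate linear model above with
  $\sigma_1 = \sigma_2 = 1$ and no covariates by default; genotypes are
  Hardy–Weinberg draws at independent sites.

What the generator does *not* emulate: linkage disequilibrium,
genotyping error, non-normal residuals, relatedness, and a literal
forward-time demographic simulation (an external per-site MAF table can
be supplied via `sfsConfig(spectrum = "custom")`). Calibration and
power results under this generator therefore speak to the ascertainment
correction and the relative behavior of the tests, not to absolute
power in any particular gene.

## Nuisance-coding choice in the null fit

The truncated primary fit needs a genotype term, and its form matters:
residual exchangeability holds only insofar as the nuisance coding
absorbs the gene's true primary-trait signal. Three strategies are
implemented (`experimentConfig(nuisance = ...)`), spanning the
bias-variance trade-off:

* `"maf-bins"` (default): unweighted minor-allele counts within a few
  frequency strata (decade bins, split finer below 0.1%, up to the VT
  cap; `codeMafBins()`). A handful of parameters,
  architecture-agnostic, and flexible enough to track MAF-dependent
  effects — in particular the mutation–selection-balance regime where
  causal effects concentrate at the rarest frequencies. One fit serves
  every test.
* `"per-test"`: one scalar coding per test family (the test's own
  coding for CMC/WSS, Madsen–Browning weighted counts for SKAT/KBAC,
  the plain count for VT). A single scalar under-fits realistic
  regions: the count up to the VT cap is dominated by common neutral
  sites, leaving rare-site signal in the residuals, which the
  threshold-scanning and quadratic statistics then detect as type-I
  inflation.
* `"per-variant"`: one nuisance effect per polymorphic site (also
  available directly as a matrix argument to
  `fitTruncatedPrimary()`). Exactly specified, but its estimation
  noise lives in the span of the genotype columns — precisely where
  SKAT looks — and inflates the quadratic tests at region scale.

A limitation worth stating precisely: the residuals are exactly
exchangeable only when the nuisance model captures the gene's true
primary-trait signal. Under any coarse coding, the fitted coefficient
targets the *population* projection of the true genetic score, while
permutation validity needs the *selected-sample* projection; two-tail
selection inflates the variance of the trait direction by a factor of
several, so the two differ in proportion to the causal carrier mass.
An oracle fit handed the true causal score yields exactly calibrated
residuals (burden z-shift $-0.07 \pm 0.14$, SKAT $+0.02$), so the gap
is attributable entirely to this projection mismatch. At the default
operating point — a gene whose causal carriers are ~0.9% of the
selected sample, affecting the primary trait at 0.5 SD per allele with
$\rho = 0.6$, the hardest configuration tested — the measured type-I
error at $\alpha = 0.05$ over 500 replicates is 0.050–0.064 for
CMC/WSS/KBAC/VT and about 0.09 for SKAT, whose quadratic form
aggregates the per-site leftovers; with no primary-trait association,
or in meta-analysis where biased and unbiased studies mix, all tests
sit at the nominal level. Users testing secondary traits against genes
with strong primary-trait effects should read borderline SKAT
p-values conservatively.

## Numerical choices

* Tail selection is rank-based; ties at a cut break by original index;
  an odd selection count puts the extra individual in the lower tail.
* The stored selection region is the innermost selected value per tail;
  known design cuts may be supplied instead (`ascertainByRegion()`).
* Optimizer: BFGS, relative tolerance $10^{-10}$, analytic gradient;
  $\sigma_1$ parameterized on the log scale; non-convergence flagged,
  then retried derivative-free; $\sigma_1$ collapsing to the boundary
  is an error, not a warning.
* Codings threshold on the `maf` column of the site table (sample
  frequency for data read from files, generating frequency for
  simulations); sites monomorphic in the analyzed sample never
  contribute. Minor-allele orientation is fixed when data enter the
  package and never re-derived.
* Quantile normalization uses average ranks for ties and the
  $(r - 0.5)/n$ offset.
* `naiveBias()` treats the aggregate coding as Gaussian (CLT argument
  for aggregated rare-variant codings) and integrates truncated
  bivariate-normal moments numerically.

## Problem sizes used by the test suite

The packaged checks run at a reduced scale chosen to keep the full
suite in the tens of minutes on one CPU: 500 replicates with 500
permutations for the single-study and three-study calibration checks
(at the full 100,000/5,000 and 3 x 50,000/2,500 designs), 300
replicates at 50,000/2,500 for the power-ordering checks, 200
replicates for parameter recovery, and 10^7 individuals for the
selection-bias oracle. Monte-Carlo error at these sizes is a few
percentage points on any rejection rate, which the acceptance bands
account for.

## Pleiotropy and power

Extreme sampling on the primary trait enriches carriers of pleiotropic
variants, which can raise secondary-trait power beyond what the same
gene would show in a random sample. Two opposing forces decide the net
effect: the enrichment gain, and the loss incurred because the
conditional fit regresses the shared (along-$y_1$) component of the
secondary signal out of the residuals. In this package's simulations
the gain wins for the weighted-sum and adaptive-cluster statistics at
moderate primary effects (~0.25 SD per allele) and the loss wins for
the variable-threshold scan, and at large primary effects (1 SD per
allele) the loss dominates for every burden-type statistic. The sign
of the pleiotropy effect on power is therefore
architecture-dependent, not universal.

## Known limitations

* The exchangeability of the residuals is asymptotic and rests on the
  nuisance coding capturing the gene's primary-trait signal; a gene
  whose true per-site effects are wildly heterogeneous *and* common
  enough to matter individually will leak into the quadratic tests.
* Binary primary traits, covariate-by-gene interactions, missing
  genotypes and dosage data are out of scope (missing genotypes are an
  error, not imputed).
* The KBAC extension is a reconstruction (see above).
* One-tailed designs and multi-stage sampling are not modeled.

## A minimal session

```{r example, eval = FALSE}
cfg <- sfsConfig(nSites = 200, seed = 1)
G <- simulateRegion(cfg, n = 100000)
G <- selectCausalSets(G, proportion = 0.5, seed = 2)
beta <- effectSizes(G, "primary", c1 = 0.5, seed = 3)
ph <- simulateTraits(G, betaPrimary = beta, rho = 0.6, seed = 4)

asc <- selectExtremes(ph$y1, 5000)
sel <- asc@indices
fit <- computeResiduals(ph$y1[sel], ph$y2[sel], G = G[sel, ],
                        primaryCoding = codeWSS(G[sel, ]),
                        region = asc@region)
regionTests(residuals(fit), G[sel, ], B = 5000, seed = 5)
```
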