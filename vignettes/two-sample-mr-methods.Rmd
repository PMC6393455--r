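---
title: "Methods: two-sample MR of vitamin D status and fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of vitamin D status and fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

# The design

`vitdmr` implements two-sample Mendelian randomization (MR) for a
continuous, standardized log-scale exposure — circulating
25-hydroxyvitamin D (25OHD) is the motivating case — and a binary or
ordinal outcome such as self-reported fatigue. The two "samples" are an
exposure GWAS (per-SNP effects on standardized log 25OHD, in SD units
per effect allele) and an independent outcome GWAS (per-SNP log-odds of
case status). The MR assumptions are the usual three: instruments are
(a) robustly associated with the exposure, (b) independent of
exposure–outcome confounders, and (c) affect the outcome only through
the exposure. (a) is addressed by instrument selection upstream; (b)
and (c) are untestable and motivate the sensitivity toolbox below.

# Harmonization and the decreasing-allele convention

Summary statistics from two studies rarely agree on which allele is the
"effect" allele. `harmonize()` first aligns the outcome study to the
exposure study's allele labels (flipping the outcome beta and
complementing its frequency when the labels are swapped; SNPs whose
unordered allele pairs disagree are dropped and reported — strand
inference from LD proxies is deliberately out of scope). Palindromic
SNPs (A/T, C/G) confound label and strand; the default policy resolves
them by effect-allele frequency concordance and drops SNPs whose
frequency is missing in either study or falls within 0.08 of 0.5 (the
conventional ambiguity zone). The window is configurable; the seven
25OHD instruments contain no palindromic pair, so the default matters
only for general use.

Every retained instrument is then oriented so its effect allele is the
**exposure-decreasing** allele: wherever the matched exposure beta is
positive the alleles are swapped, the outcome beta is negated, and the
exposure beta is stored as a positive magnitude per decreasing allele.
Two things follow. First, all downstream slopes read as log-odds per
1-SD *decrease* in the exposure, which is the direction in which a
protective effect of vitamin D on fatigue would appear as OR > 1.
Second, MR-Egger's requirement that all exposure betas share one sign
is satisfied by construction.

## Rescaling externally sourced betas

One instrument's exposure effect may come from a different GWAS than
the rest (for 25OHD, the low-frequency *CYP2R1* variant rs117913124 is
only available from an earlier meta-analysis). `rescale_external_beta()`
maps it onto the reference scale by regressing the reference study's
betas on the source study's betas across their shared SNPs and
multiplying the target's beta and SE by the fitted slope, which leaves
the z-score unchanged. Two genuinely open choices were settled as
follows: the regression is **through the origin** (both scales measure
the same standardized quantity, so they must agree at zero, and an
intercept fitted on a handful of points would mostly absorb noise), and
the direction is **reference-on-source** (the slope then directly
multiplies source-scale quantities). With proportional scales either
direction gives reciprocal slopes; with noise the chosen direction is
the one whose fitted value is applied multiplicatively, which keeps the
procedure idempotent for already-matching scales.

# Estimators

With harmonized pairs `(bx_j, sx_j, by_j, sy_j)`, Wald ratios
`r_j = by_j / bx_j`, and weights `w_j = bx_j^2 / sy_j^2`:

- **Wald ratio** (single SNP): SE `sy_j / |bx_j|`, the first-order
  delta method. The exposure-side term enters at second order and is
  ignored, as is conventional in two-sample MR where instruments are
  genome-wide significant; the test suite verifies by Monte Carlo that
  the first-order SE is within 5% of the sampling SD when
  `sx/bx < 0.1`.
- **IVW**: the `w`-weighted mean of the `r_j`, algebraically the
  weighted through-origin regression of `by` on `bx`. The default is
  the fixed-effect SE `(Σw)^{-1/2}`; the multiplicative-random-effects
  variant multiplies it by the residual SD floored at 1. The floor
  means the two variants coincide whenever Q ≤ df, so for a
  well-behaved instrument set the choice is immaterial — which is why
  fixed-effect is the default rather than a substantive commitment.
- **Weighted median**: order the ratios, form cumulative weight
  midpoints `p_j = S_j − w'_j/2`, and linearly interpolate at 0.5
  (ratios outside the midpoint range take the boundary ratio). The SE
  is a parametric bootstrap: betas resampled from
  `N(observed, SE)` on both sides, weights recomputed, the median
  recomputed; default 5000 resamples, and a seed is mandatory so runs
  are reproducible. Penalized weights are not applied (the plain
  weighted median is the estimator of record here).
- **MR-Egger**: weighted least squares of `by` on `bx` with intercept,
  weights `1/sy^2`. Coefficient SEs use the WLS residual SD floored at
  1, mirroring the IVW convention, so Egger never reports less
  uncertainty than pure sampling noise implies. Inference uses the
  normal reference distribution by default with a `t(k−2)` option; with
  k = 7 instruments the t reference is noticeably more conservative,
  and both are exposed because neither is canonical in the applied
  literature.

**Cochran's Q** is computed against the IVW estimate with the same
weights, with `I² = max(0, (Q−df)/Q)·100` and the DerSimonian–Laird
moment estimate of `τ²`. P-values are two-sided throughout the
package.

# Sensitivity toolbox

`mr_leave_one_out()` re-estimates with each instrument omitted
(identical estimator options across rows); `mr_single_snp()` gives the
per-instrument forest, whose IVW pooling reproduces `mr_ivw()` exactly
(tested as an algebraic identity). `mr_bidirectional()` orchestrates
harmonization and estimation in both causal directions with independent
instrument sets, warning (not failing) on overlap. `build_prs()` forms
the weighted allele score `Σ_j β_j g_ij` — on the standardized
log-exposure scale when exposure betas are the weights — and
`confounder_check()` regresses it on a putative confounder, reporting
the overall model F-test p-value and per-stratum means and SDs (the
tabular content of the usual stratified boxplot; the package
deliberately emits tables, not graphics). These checks operate on
individual-level data, which in practice means the synthetic cohorts:
the contract is the statistical procedure, not any particular cohort's
result.

# Power and meta-analysis

`power_binary_mr()` implements the non-centrality approximation for an
IV analysis of a binary outcome: with case proportion K and odds ratio
OR per 1-SD exposure change,
`b = K(OR/(1+K(OR−1)) − 1)`, `v = (K(1−K) − b²)/(N·r²)`, and power is
the upper tail of `χ²₁(ncp = b²/v)` beyond the central critical value.
It is monotone in N, r² and |log OR| (property-tested).

`dl_meta()` pools standardized mean differences with DerSimonian–Laird
random effects; SEs are recovered from printed 95% CIs via
`(high − low)/(2·1.959964)` when not supplied directly. The pooled
estimate is reported with the sign implied by the inputs, and the
fixed-effect pool is retained alongside. The bundled `fatigue_rcts()`
table carries the three published vitamin D supplementation trials that
reported fatigue change scores; because its inputs are CIs printed to
two decimals, recomputed heterogeneity statistics can differ from
originally published ones in the first decimal.

# The synthetic generator

`simulate_cohorts()` emulates the study conditions the pipeline is
meant for, with every default chosen once as the emulated condition:

- **Two disjoint cohorts** with independent noise: exposure study
  n = 20,000, outcome study n = 50,000 by default. These are desk-scale
  stand-ins for a GWAS meta-analysis (~80k) and a biobank (~330k):
  large enough that instrument strength and case counts are realistic
  in kind, small enough that replicated simulation studies are
  routine. Larger sizes are a config field away.
- **7 independent biallelic SNPs** with MAF uniform on (0.10, 0.45),
  non-palindromic allele pairs, Hardy–Weinberg binomial dosages, and
  fixed relative effect magnitudes `(3, 1.2, …, 0.6)` scaled so the
  instruments jointly explain **5%** of exposure variance. The skewed
  pattern mirrors the real 25OHD instrument set, where the *GC* locus
  carries a large share of the explained variance; effect signs are
  random because orientation is harmonize's job and the real code path
  should be exercised.
- **Exposure** `X = G − E[G] + c_e·U + e` with population variance 1
  (mean ≈ 0, SD ≈ 1 within sampling error). The exposure is generated
  directly on the standardized scale rather than by log-transforming a
  lognormal, since every quantity of interest is per 1-SD of the
  standardized log scale.
- **Ordinal outcome** from a latent-logistic threshold model with
  linear predictor `η = θ·(−X') + Σ_j δ_j g*_j + c_o·U`, where `X'` is
  the outcome cohort's own (unobserved) exposure analogue, `g*_j` the
  exposure-decreasing-allele dosage and `δ_j ~ N(δ̄, σ_δ)` the per-SNP
  direct effects — applied on the decreasing-allele orientation so a
  non-zero `δ̄` is *directional* pleiotropy in exactly the sense the
  Egger intercept targets. The three thresholds are solved numerically
  (uniroot on the mean latent exceedance probability) so the marginal
  category frequencies hit 47.31 / 40.98 / 5.75 / 5.96 percent, the
  top ("nearly every day") category matching the 5.96% case
  prevalence. Because the top threshold is placed this way,
  dichotomizing at the top category yields an exactly logistic binary
  outcome — the per-SNP logistic scan is then correctly specified up to
  the marginalization over the latent exposure.
- **Confounding**: a shared standard-normal confounder loads on
  exposure (0.25 SD) and outcome logit (0.25) by default — present
  because MR's whole point is robustness to it, harmless to the
  estimators because instruments are independent of it.
- **Covariates**: sex, a 5-level centre-like factor and 3 PC-like
  standard-normal variates are generated inert, for exercising the
  covariate-adjusted scans and the confounder checks.

`gwas_continuous()` runs per-SNP OLS (QR-based, closed-form),
`gwas_logistic()` per-SNP maximum-likelihood logistic regression (IRLS
to a 1e-10 deviance tolerance, Wald SEs from the information at the
converged fit). SNPs that are monomorphic, separated or non-converged
have no valid association row and are dropped with a warning naming
them — the summary-statistic container requires finite betas and
positive SEs, so "reported and excluded" is the honest representation.

**What the generator does not emulate**: linkage disequilibrium between
instruments, sample overlap between the two studies, imputation dosage
uncertainty, genuine population stratification (the PC-like covariates
are inert), winner's-curse selection of instruments, and assortative
mating. Passing simulation tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to these
additional real-data complications.

# What the test suite establishes

Beyond per-operation oracle checks (closed-form normal equations for
IVW/Egger/Q at 1e-10; an independent Newton–Raphson logistic fit;
scramble-and-recover over all 8 allele-flip combinations per SNP), the
suite runs full-loop simulation studies at the default study scale:
500 replicates across true effects θ ∈ {0, 0.1, 0.3} without
pleiotropy, requiring IVW 95% CI coverage of θ within [0.92, 0.98] and
providing the Egger intercept's null rejection rate; plus 250
replicates with directional pleiotropy (δ̄ = 0.02, σ_δ = 0.005),
requiring the Egger rejection rate to exceed the null rate at least
threefold. These replicate counts keep the whole suite around ten minutes
on one CPU while keeping the binomial noise on each estimated rate
small relative to the asserted margins.

# Known limitations

- The first-order Wald SE and the NOME-style IVW weights ignore
  exposure-side uncertainty; with per-SNP F-statistics in the hundreds
  (as here) the neglected terms are second-order small.
- The marginal per-SNP logistic coefficient is mildly attenuated
  relative to the conditional one (non-collapsibility); at the default
  prevalence and effect sizes the bias is an order of magnitude below
  the estimator's SE, which the coverage study confirms in aggregate.
- MR-PRESSO-style outlier removal, mode-based estimators, multivariable
  and LD-aware MR are out of scope.
- The continuous-outcome sensitivity variant codes the four ordinal
  categories as 0–3 and runs per-SNP OLS; this equal-spacing coding is
  a documented convention, not an inference about the latent scale.
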