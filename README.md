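# vitdmr

Two-sample Mendelian randomization (MR) of vitamin D status and
self-reported fatigue, as a tested and reusable R pipeline.

Observational studies link low circulating 25-hydroxyvitamin D (25OHD)
to feeling tired, and fatigue is one of the most common reasons for
vitamin D testing and supplementation — but the association is easily
confounded (lifestyle, adiposity, time outdoors) and runs both ways
(fatigued people get less sun). MR sidesteps both problems by using
genetic variants that lower 25OHD as instruments: because genotypes are
fixed at conception, an effect of 25OHD-lowering alleles on fatigue is
evidence for a causal effect of 25OHD itself. `vitdmr` implements the
full analysis for this design — and for two-sample MR with GWAS summary
statistics generally — together with a synthetic two-sample GWAS
generator with known ground truth, so that every stage is testable
without access to cohort data.

## The model

For SNP *j*, let `β̂_Xj` (SE `σ_Xj`) be its effect on the standardized
log-scale exposure and `β̂_Yj` (SE `σ_Yj`) its log-odds effect on the
binary outcome, both harmonized so the effect allele is the
exposure-*decreasing* allele (so causal effects read per 1-SD decrease
in the exposure). The per-SNP Wald ratio is `r_j = β̂_Yj / β̂_Xj` with
first-order SE `σ_Yj / |β̂_Xj|`, and with weights
`w_j = β̂_Xj² / σ_Yj²`:

- **IVW**: `β̂ = Σ w_j r_j / Σ w_j`, `SE = (Σ w_j)^(-1/2)` (fixed
  effect; a multiplicative-random-effects variant scales the SE by the
  residual SD of the equivalent weighted through-origin regression,
  floored at 1). Consistent when all instruments are valid.
- **Weighted median**: the 50% point of the weighted empirical
  distribution of the `r_j` (cumulative-midpoint interpolation),
  bootstrap SE. Consistent when valid instruments carry ≥ 50% of the
  weight.
- **MR-Egger**: weighted regression `β̂_Yj = a + b·β̂_Xj` with weights
  `1/σ_Yj²`. The slope `b` is pleiotropy-robust under InSIDE; the
  intercept `a` estimates directional (unbalanced) horizontal
  pleiotropy.

Diagnostics and sensitivity analyses: Cochran's Q / I² / τ² across the
ratio estimates, leave-one-out and single-SNP tables, bidirectional MR,
and association checks of the weighted polygenic score against putative
confounders. Auxiliary tools: analytic MR power for a binary outcome
(non-centrality approximation) and DerSimonian–Laird random-effects
meta-analysis of standardized mean differences for the supplementation
RCTs.

## Worked example

```r
library(vitdmr)

# A synthetic two-sample study with a known causal effect of 0.1
# log-odds per 1-SD exposure decrease:
co <- simulate_cohorts(sim_config(seed = 7, causal_beta = 0.1))
exposure_gwas <- gwas_continuous(co$exposure)   # per-SNP OLS, n = 20,000
outcome_gwas  <- gwas_logistic(co$outcome)      # per-SNP logistic, n = 50,000

report <- run_analysis(analysis_config(exposure = exposure_gwas,
                                       outcome = outcome_gwas, seed = 7))
report
#> Two-sample MR run
#>
#> Estimates (OR per 1-SD exposure decrease):
#>   threshold          method          or_95ci pvalue n_snps
#> 1   primary       ivw_fixed 1.02 (0.87-1.20)  0.782      7
#> 2   primary weighted_median 1.03 (0.86-1.23)  0.737      7
#> 3   primary     egger_slope 1.11 (0.82-1.51)  0.484      7
#>
#> Cochran's Q = 4.339 on 6 df (p = 0.631), I^2 = 0.0%, tau^2 = 0
#> Egger intercept -0.01492 (SE 0.02283, p = 0.513)
```

All three estimators agree, their CIs cover the true odds ratio
`exp(0.1) ≈ 1.11`, Q shows no heterogeneity across instruments, and the
Egger intercept is compatible with zero — exactly what a valid,
modestly powered instrument set should produce. The report also carries
leave-one-out and single-SNP tables and the scatter-table behind the
usual MR scatter plot.

The auxiliary analyses reproduce in one line each:

```r
dl_meta(fatigue_rcts())
#> Random-effects (DerSimonian-Laird) meta-analysis of 3 studies
#>   pooled SMD -0.293 (95% CI -0.830, 0.243), p = 0.284
#>   Q = 8.779 on 2 df (p_het = 0.0124), I^2 = 77.2%, tau^2 = 0.1714

power_binary_mr(n = 327478, alpha = 0.05, k_prev = 0.0596,
                odds_ratio = 1.10, r2 = 0.05)
#> [1] 0.8536727
```

The pooled RCT evidence on vitamin D supplementation and fatigue is
heterogeneous and inconclusive (I² = 77%), and a binary-outcome MR with
327,478 individuals, 5.96% cases and instruments explaining 5% of
exposure variance has 85% power to detect an odds ratio of 1.10.

A bundled fixture `vitd_instruments_synthetic()` carries the seven
canonical 25OHD instruments (rs3755967, rs12785878, rs10741657,
rs17216707, rs117913124, rs8018720, rs10745742) with *synthetic* effect
sizes for examples and pipeline exercises; see its help page.

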