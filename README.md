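# ivmr

Two-sample Mendelian randomization (MR) from GWAS summary statistics, for
epidemiologists and statistical geneticists who want the full estimator and
diagnostic stack — instrument filtering, allele harmonization, IVW,
weighted-median, MR-Egger, MR-PRESSO, heterogeneity and leave-one-out
diagnostics, and binary-outcome power calculation — as plain, tested R with
no web-service dependencies.

## The model

Genetic variants G₁…G_k serve as instrumental variables for an exposure X
(in SD units) on a binary outcome Y (log-odds). Each variant contributes a
Wald ratio

    r_i = β_out,i / β_exp,i ,   se(r_i) ≈ se_out,i / |β_exp,i| ,

valid when the variant (1) associates with X, (2) is independent of
confounders, and (3) affects Y only through X. The primary estimator is
the inverse-variance-weighted (IVW) meta-analysis of the ratios,

    β̂_IVW = Σ w_i r_i / Σ w_i ,   w_i = β_exp,i² / se_out,i² ,

equivalent to weighted least squares of β_out on β_exp through the origin
with weights 1/se_out². By default the standard error is inflated by
max(1, √(Q/(k−1))) (multiplicative random effects), where
Q = Σ w_i (r_i − β̂_IVW)² is Cochran's heterogeneity statistic. Assumptions
(2)–(3) are probed by the weighted-median estimator (consistent when at
least half the weight comes from valid instruments), MR-Egger regression
(a free intercept absorbs — and tests — average directional pleiotropy),
MR-PRESSO (simulation-based residual-sum-of-squares outlier test with
outlier-corrected re-estimation), and leave-one-out refits. Power for a
binary outcome uses the non-centrality-parameter formulation with the
attenuated effect b = K(OR/(1 + K(OR − 1)) − 1), K the case fraction.

The package ships the published instruments for three calcium-pathway
exposures — serum 25-hydroxyvitamin D (25OHD, 6 SNPs), serum calcium
(7 SNPs) and parathyroid hormone (PTH, 5 SNPs) — against coronary artery
disease (CAD) in 15,666 diabetic individuals (3,968 cases), as worked
example data.

## Worked example

```r
library(ivmr)

d <- mr_fixture("25OHD")        # 6 instruments, harmonized
fit <- mr_fit(d, seed = 42)     # all estimators + diagnostics
fit
#> Two-sample MR fit: S-25OHD -> CAD in diabetes (6 SNPs)
#>
#>           method nsnp    or          ci pvalue
#>          ivw_mre    6 1.054 0.594-1.872  0.857
#>  weighted_median    6 1.276 0.705-2.308  0.421
#>      egger_slope    6 1.807 0.696-4.691  0.291
#>
#> Cochran's Q = 5.62 (df 5), P = 0.345; Egger intercept P = 0.250
#> MR-PRESSO global P = 0.112 (no outliers)
```

Reading: per SD-unit increase in genetically predicted serum 25OHD, the
odds of CAD in diabetes change by a factor of 1.05 (95% CI 0.59–1.87) —
no evidence of a causal effect, and the robust estimators, the absence of
heterogeneity (Q = 5.62, P = 0.345), of directional pleiotropy (Egger
intercept P = 0.250) and of outliers all agree. The minimum detectable
effect at 80% power given the instruments' 0.46% explained variance:

```r
mr_detectable_or(15666, 3968, r2 = 0.0046)
#> [1] 1.881534
```

`mr_reproduce(seed = 1)` runs all three exposures end-to-end, adds the
power panel and a 0.05/3 Bonferroni significance flag, and (with
`out_dir=`) writes byte-reproducible TSV reports. `mr_analyze()` does the
same for your own pair of summary-statistics files;
`mr_simulate_pair(mr_sim_config(...))` generates two-sample summary
statistics with known ground truth (pleiotropy, planted outliers) for
method evaluation.

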