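---
title: "Methods: two-sample Mendelian randomization in ivmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in ivmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmr)
```

## The causal model and its assumptions

Two-sample Mendelian randomization estimates the causal effect of an
exposure $X$ (standardized, SD units) on a binary outcome $Y$ (log-odds
scale) from two independent GWAS: one reporting per-allele effects
$\hat\beta_{X,i} \pm \sigma_{X,i}$ of $k$ variants on the exposure, one
reporting effects $\hat\beta_{Y,i} \pm \sigma_{Y,i}$ of the same variants
on the outcome. Each variant is a valid instrument when it is (1)
associated with the exposure, (2) independent of exposure–outcome
confounders, and (3) affects the outcome only through the exposure.
`significance_filter()` enforces (1) by keeping variants with exposure
$p < 5\times10^{-8}$ (strict inequality, the conventional genome-wide
level). (2) and (3) cannot be enforced from summary data; the diagnostics
below probe their violation. Instruments are assumed LD-independent
(pre-pruned); the package performs no LD computation.

Under the model $\hat\beta_{Y,i} \approx \beta\,\hat\beta_{X,i}$, each
variant yields a Wald ratio $r_i = \hat\beta_{Y,i}/\hat\beta_{X,i}$ with
first-order (delta-method) standard error
$\sigma_{Y,i}/|\hat\beta_{X,i}|$. First-order weights ignore
$\sigma_{X,i}$; this is the standard choice when instruments are strong
(here exposure $|z|$ ranges from roughly 6 to 45), and second-order or
exact weights are deliberately out of scope.

## Estimators

**IVW.** $\hat\beta = \sum w_i r_i / \sum w_i$ with
$w_i = \hat\beta_{X,i}^2/\sigma_{Y,i}^2$, identical to weighted least
squares of $\hat\beta_Y$ on $\hat\beta_X$ through the origin with weights
$1/\sigma_Y^2$. Two SE modes share this point estimate: `fixed`,
$SE = (\sum w_i)^{-1/2}$, and the default `multiplicative_random`, which
inflates by $\max(1, \sqrt{Q/(k-1)})$ with $Q$ Cochran's statistic. The
floor at 1 credits no under-dispersion. The multiplicative random-effects
default matches the dominant community convention for primary MR
analyses; both modes are exported side by side.

**Weighted median.** Ratios are sorted; with normalized weights $w_i'$
the cumulative midpoints $s_i = \sum_{j\le i} w_j' - w_i'/2$ define a
piecewise-linear quantile function, interpolated at $s = 0.5$. Outside
$[s_1, s_k]$ the boundary ratio is returned, so concentrating all weight
on one variant returns that variant's ratio. The SE is the standard
deviation over `n_boot` parametric-bootstrap replicates (default 1000)
redrawing every $\hat\beta_{X,i}$ and $\hat\beta_{Y,i}$ from normal
distributions at their observed means and SEs; the seed is a required
argument, making the SE bit-reproducible. A resampled exposure beta of
exactly zero (probability zero in theory, possible in floating point) is
nudged to the smallest positive double rather than dropped.

**MR-Egger.** Weighted least squares with a free intercept, weights
$1/\sigma_Y^2$, solved from the normal equations. The intercept estimates
average directional pleiotropy; the slope is the causal estimate under
the InSIDE assumption. Both SEs are inflated by
$\max(1,\sqrt{RSS_w/(k-2)})$. P-values use the $t$ distribution with
$k-2$ degrees of freedom rather than the normal: with $k$ between 5 and
7 a two-parameter weighted regression has very few residual degrees of
freedom, the $t$ reference is the exact small-sample distribution under
weighted-normal errors, and it is what the widely used MR toolchains
report. Confidence intervals throughout the package use the 1.959964
normal quantile, the convention in which MR results are reported.
Degenerate designs (all exposure betas equal) are rejected as collinear.

## Diagnostics

**Cochran's Q** with the IVW ratios and weights, $df = k-1$, upper-tail
chi-square p-value. **Funnel coordinates** (`mr_single_snp()`): ratio
versus precision $1/se$, exported as a table rather than drawn.
**Leave-one-out**: the IVW estimate recomputed $k$ times dropping one
variant each, exposing single-variant leverage.

**MR-PRESSO.** The observed statistic is
$RSS = \sum_i \sigma_{Y,i}^{-2}\,(\hat\beta_{Y,i} -
\hat\beta_{(-i)}\hat\beta_{X,i})^2$ with $\hat\beta_{(-i)}$ the
fixed-effect IVW slope excluding variant $i$, so no variant contributes
to its own prediction. The null distribution is a parametric bootstrap:
`n_sim` homogeneous datasets drawn as
$\beta_{X,i}^* \sim N(\hat\beta_{X,i}, \sigma_{X,i})$,
$\beta_{Y,i}^* \sim N(\hat\beta_{IVW}\hat\beta_{X,i}, \sigma_{Y,i})$,
with the statistic — leave-one-out slopes included — recomputed in full
on each. Simulating around the *common* pooled slope, rather than around
each variant's own leave-one-out prediction, is a deliberate design
choice: the statistic is invariant to the common slope, so the bootstrap
is calibrated regardless of the pooled estimate's accuracy, and the
simulated null cannot inherit an outlier's distortion through the
per-variant leave-one-out means (per-variant null means reproduce
neither property — they double-count slope noise under homogeneity and
embed the outlier's pull under contamination; both failure modes were
confirmed by simulation at this package's test scales). The global
p-value uses the add-one estimator $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$
and is never zero. Each variant's squared weighted residual is compared
with its own simulated distribution, flagged as an outlier below
$\alpha/k$ (Bonferroni, $\alpha = 0.05$ by default — conventions differ
between implementations, so this is an explicit configuration value);
flagged variants are removed and IVW is re-run for the corrected
estimate. Under heavy single-variant contamination some valid
instruments can be swamped into the flag set (their observed residuals
are measured against leave-one-out slopes the outlier still pulls); the
corrected estimate remains consistent as long as valid instruments
survive, and if every variant is flagged the corrected estimate is
withheld with a warning. The distortion test (bootstrap p-value for the
raw-minus-corrected difference) is implemented but off by default.

## Harmonization

`harmonize()` inner-joins on rsid and re-expresses the outcome effect per
copy of the exposure study's effect allele: swapped alleles negate the
outcome beta and complement its allele frequency (an involution); alleles
matching only after strand complement are resolved before concluding;
palindromic variants (A/T, C/G) whose exposure-side frequency lies within
0.08 of 0.5 (i.e. in [0.42, 0.58]) are dropped as strand-ambiguous — 0.08
is the common community window; anything irreconcilable is dropped. Every
non-trivial action is logged per variant. Datasets are stored in their
published orientation: slope estimators are invariant to jointly flipping
a variant's two betas, but the Egger intercept is not, so re-orientation
to non-negative exposure effects is a user flag (`reorient`), off by
default.

Two file-format choices deserve note. P-values below the double-precision
range (GWAS tables legitimately print values like 1e-343) underflow to 0
when parsed; the reader clamps such values to the smallest positive
double so the strict-positivity invariant survives. And the p-value/z
consistency check is a warning computed on the z scale (implied $|z|$
differing by more than a factor of 2 and by more than 1), because
published tables round beta and SE to a few decimals, which distorts tail
p-values by many orders of magnitude while barely moving $z$.

The bundled instrument tables carry the exposure-study effect-allele
frequency only; outcome frequencies are not published for these studies
and no estimator consumes them, so the outcome fixtures store `NA` rather
than an invented value.

## Power

`mr_power_binary()` implements the non-centrality-parameter calculation
for a binary outcome: with case fraction $K$, attenuated effect
$b = K\,(OR/(1+K(OR-1)) - 1)$, variance $v = (K(1-K)-b^2)/(N r^2)$, the
test statistic is $\chi^2_1(ncp = b^2/v)$ against the central
$1-\alpha$ quantile. The formula degenerates when $|b| \ge \sqrt{K(1-K)}$
(v non-positive), which at $K \approx 0.25$ happens above $OR \approx 4$;
`mr_detectable_or()` therefore bisects on
$[1+10^{-6}, \min(50, OR_{max})]$ where $OR_{max}$ is the positivity
boundary, to $10^{-6}$ absolute tolerance, and reports the attainable
power range if the target lies outside it. Power is strictly increasing
in OR on this bracket, which guarantees the bisection. Protective
effects use the mirrored bracket below 1.

## The synthetic-data generator

`mr_sim_config()` fixes per-variant instrument effects $\gamma_i$ (given
explicitly or drawn once, uniformly, from a range using the config seed)
and simulates studies as $\hat\beta_{X,i} \sim N(\gamma_i, \sigma_{X,i})$
and $\hat\beta_{Y,i} \sim N(\Gamma_i, \sigma_{Y,i})$ with
$\Gamma_i = \beta\gamma_i + \alpha_i + \text{outlier shift}$, where the
direct effects $\alpha_i$ are zero, mean-zero normal (balanced
pleiotropy) or mean-shifted normal (directional pleiotropy). Keeping
instruments fixed across noise seeds isolates sampling variation, the
standard two-sample asymptotic regime. Alleles alternate A/G (never
palindromic) and frequencies are drawn once per config, purely to
exercise the I/O layer; no estimator consumes them.
`mr_sim_config_matched()` copies a bundled instrument set's effect sizes
and SEs so simulations run at exactly the precision regime of the worked
example. The generator emulates independent instruments with normal
sampling noise and no sample overlap; it does not model LD, winner's
curse, or allele-frequency-dependent SEs, so passing tests demonstrate
estimator correctness under the stated model, not robustness to those
real-data features.

## Test scales and numerical conventions

The test suite exercises the statistical properties at sizes chosen to
keep the whole suite under a few minutes on one CPU while leaving
Monte-Carlo error well inside the asserted bands: 500 replicates for
IVW bias/coverage and type-I checks and for MR-PRESSO null calibration
(with 200 simulations per test), 100 seeds for planted-outlier recovery
(500 simulations each, 10-residual-SD outliers), and 20–30 random
instances for exact oracle-equivalence checks (tolerance $10^{-8}$
against independently coded brute-force implementations of the weighted
median and the Egger normal equations). Bootstrap and simulation
p-values use add-one estimators; all report files round to 6 significant
digits with fixed orderings, making regeneration under a fixed seed
byte-identical; all confidence intervals use the 1.959964 quantile;
two-sided p-values are floored at the smallest positive double.

## Known limitations

Single-exposure, single-outcome analyses only — no multivariable MR, no
SIMEX correction for Egger, no mode-based estimators, no Steiger
filtering, no I² or model-selection frameworks. Harmonization resolves
strand by allele complement and frequency only; no proxy lookup or
coordinate liftover. The power routine covers binary outcomes only. The
weighted-median SE depends on the bootstrap seed, so numerically exact
agreement with other software is not expected (point estimates agree
exactly).
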