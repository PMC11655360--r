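---
title: "Optimizing BWAS designs: effect sizes, sampling schemes and replicability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing BWAS designs: effect sizes, sampling schemes and replicability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwasdesign)
```

## The problem

Brain-wide association studies (BWAS) regress brain measures (regional
volumes, cortical thickness, functional connectivity) on behavioural and
demographic covariates across many participants. Reported standardized
effect sizes in BWAS are small, and replicability correspondingly poor,
which has motivated calls for ever-larger samples. Sample size, however, is
only one design lever. The variability of the covariate — how participants
are spread across age or a behavioural score, both between subjects and
within subjects over repeated visits — directly scales the standardized
effect size, and it can be manipulated at design time through targeted
sampling. This package provides the statistical machinery for reasoning
about those levers: robust standardized effect sizes, design-targeted
resampling experiments, power and replicability conversion, and
meta-regression of effect sizes on design features.

## The effect size index

All effect sizes here are the robust effect size index (RESI). For a fitted
association model with coefficient subvector $\beta$ tested against
$H_0\!: \beta = \beta_0$ using a robust Wald statistic
$T^2 = N(\hat\beta-\beta_0)^{\top}\Sigma_\beta^{-1}(\hat\beta-\beta_0)$
(with $\Sigma_\beta$ the covariance of $\sqrt{N}\hat\beta$), the estimator is

$$\hat S = \sqrt{\max\!\left\{0,\ \frac{T^2 - m}{N}\right\}},$$

where $m$ is the number of tested parameters and $N$ the number of
*participants* — not observations, so longitudinal designs are credited for
information per subject rather than row count. Subtracting $m$ removes the
statistic's null expectation; the truncation keeps $\hat S \ge 0$. Under the
assumptions of Cohen's d (two balanced groups, equal variances),
$S = d/2$, so the conventional small/medium/large d thresholds map to RESI
0.1 / 0.25 / 0.4. Because the Wald statistic uses a sandwich covariance, the
RESI remains consistent when group variances differ and d does not.

Confidence intervals are non-parametric subject-level bootstraps: whole
subjects are resampled with replacement, the model refitted, and the
percentile interval of the replicate $\hat S$ values reported (type-1
quantiles, so at 1,000 replicates the 95% bounds are exactly the 25th and
975th order statistics). We chose the percentile interval over BCa because
the quantile rule is the contract the rest of the machinery (scheme
experiments, CS-RESI) relies on.

## Study-level models

Cross-sectional tables are fitted by least squares with an HC0 sandwich
covariance (HC3 via a flag; no small-sample correction by default because
the intended use is large-N cohort data). Longitudinal tables are fitted by
generalized estimating equations with identity link and an exchangeable
working correlation, the marginal-model standard for repeated measures. The
package implements this GEE directly as iteratively reweighted least
squares: the exchangeable inverse has the closed form
$V_i^{-1} \propto a I - b_k \mathbf{1}\mathbf{1}^{\top}$, which lets every
cluster sum be computed with grouped column sums rather than per-cluster
loops, so fits on thousands of subjects take milliseconds. Scale and
correlation parameters use the usual moment estimators; the coefficient
covariance is the subject-clustered sandwich. Convergence is declared at a
maximum coefficient change below 1e-8 within 100 iterations, and failure is
an error, never a silent fallback. With one observation per cluster the
engine reproduces the least-squares fit to ten significant digits, a
property the test suite pins down. Random-effects (mixed-model) estimation
is deliberately out of scope: the marginal GEE path is the canonical one
here and the two agree on the mean model.

The default mean model is `y ~ ns(age, df = 2) + sex`: a natural cubic
spline on age with boundary knots at the data range and one interior knot
at the median (`df = 2`), or two interior knots at the tercile boundaries
(`df = 3`, used for motion covariates and meta-regression features). Rows
with missing modelled values are dropped listwise and counted in the fit
object. Sex is coded 0/1 with 0 as reference throughout, so coefficient
signs are reproducible.

Multi-site heterogeneity is handled by a location-only residualization:
site main effects are estimated conditional on the model covariates and
subtracted, preserving covariate–outcome associations. This is a
deliberately minimal adjustment — empirical-Bayes harmonization (ComBat and
its longitudinal variant) shrinks site effects and also aligns scales, and
users with multi-site data at analysis time should prefer those published
tools; the stage here exists so the pipeline is end-to-end testable.

## Between- and within-subject effects

A single-covariate longitudinal model assumes one common association for
between-subject differences and within-subject change. When the two differ
— typical when a noisy behavioural covariate is paired with a stable
structural outcome — the single coefficient becomes a variance-weighted
average of the two and can *shrink* as within-subject variability grows.
`fit_between_within()` therefore decomposes the covariate into `X_bl` (the
subject's baseline value) and `X_change` (each visit's deviation from
baseline) and estimates both effects jointly by GEE. Anchoring the
between-subject term at baseline makes its coefficient directly comparable
to a baseline-only cross-sectional fit, and makes the two design variance
components separable: the between-subject variance is the variance of the
baseline covariate and the within-subject variance is the mean square of
`X_change`. Subjects without a baseline row are excluded, and a covariate
with no follow-up variation is an explicit error because the within effect
is then undefined.

## CS-RESI

Longitudinal and cross-sectional RESIs are not directly comparable: a
longitudinal design typically extracts more information per subject. The
cross-sectional-equivalent RESI (CS-RESI) estimates what the same study
population would have yielded cross-sectionally. The estimator implemented
is deliberately simple and assumption-light: draw one visit per subject at
random, fit the cross-sectional model, compute $\hat S$, and average over
repeated subsamples (20 by default; the average's Monte-Carlo error shrinks
as subsample draws are added, and 20 keeps the bootstrap CI affordable).
Its CI is a subject-level percentile bootstrap of the whole subsample-
averaged estimator. On a table with one visit per subject the estimator
collapses to the plain RESI exactly. A closed-form estimator of the same
quantity exists; the subsample estimator is the package's reference
implementation, and any closed form is required (by the test contract) to
agree with it within Monte-Carlo tolerance.

## Targeted sampling weights

Design experiments reweight bootstrap resamples so a covariate follows a
chosen target distribution. Weight construction has two stages. First each
record (or visit combination) is inversely weighted by its *local
frequency* — the number of records whose covariate values fall within a
closed ±0.5-unit window in every dimension — which flattens the empirical
distribution towards uniform. Then weights are rescaled by the target
density. Targets on the winsorized support, mapped to $u \in [-1, 1]$:

| family | density | role |
|---|---|---|
| bell | $(1-u^2)+\delta$ | shrink covariate variance |
| uniform | $1$ | flatten |
| u_shaped | $u^2+\delta$ | grow covariate variance |
| increasing / decreasing | $e^{\pm\lambda t},\ t \in [0,1]$ | steer within-subject change |
| binary_proportion | class weights $\propto$ target/prevalence | binary covariates |

The floor $\delta = 0.05$ keeps every record's selection probability
positive (the pure quadratic vanishes at the centre or edges); the
exponential rate $\lambda = 2$ gives roughly a 7-fold density ratio across
the change support. Both are configurable; the defaults were fixed once as
mild-but-clear shape contrasts and are not tuned per analysis.

For longitudinal tables, every (baseline, follow-up) combination per
subject is enumerated, the between-subject target acts on baseline age, the
within-subject target on the age change, and the inverse *bivariate* (or
trivariate, for two follow-ups) local frequency flattens the joint
distribution — which is what makes the two targets act independently, a
property the suite checks. Winsorization bounds clamp values *for weight
assignment only*; stored data values are never modified and every analysis
uses actual values. Bounds default to the 5%/95% sample quantiles and
should trim only genuine outliers: clamping a large share of records piles
them onto the boundary, the windowed frequency then sees a mass point, and
the between/within independence degrades. Sampling is with replacement
(the standard bootstrap), and each sampled unit becomes a fresh subject so
resampled copies are independent clusters.

`run_scheme_experiment()` wires this together: per scheme and per sample
size, B weighted resamples are drawn, the model is refitted on each, and
the mean $\hat S$, its 2.5%/97.5% percentile band, and the replicate
p-values are recorded. Replicate failures are excluded with a count, never
retried, so a given seed always maps to the same resample.

## Power, replicability, sample size

With effect size $S$, $m$ tested parameters and model degrees of freedom
$df$, the test statistic at sample size $N$ is treated as non-central
$F(m,\ N-df;\ \lambda = N S^2)$, and power is the tail mass beyond the
central-F critical value. The reference formulation fixes $m = 1$; the
implementation generalizes to joint tests and reproduces the $m = 1$ case
exactly. Replicability — the probability that two independent identically
designed studies both reject — is power squared, and required sample sizes
invert the power curve by integer bisection, so `n_for_power()` returns the
smallest $N$ whose power reaches the target and
`n_for_replicability(r)` is identically `n_for_power(sqrt(r))`. Empirical
power from scheme experiments is the share of replicates with $p \le
\alpha$, interval-estimated by Wilson's score method; following the
convention for replicability reporting, it is meant to be computed over
associations that are significant in the full data, and the pipeline's
report applies that filter.

## Meta-regression of effect sizes

Study-level effect sizes are regressed on design features — design type
indicator plus df=3 natural splines of mean age, SD of age and skewness of
age (or proportion male for sex effects) — by weighted least squares with
heteroskedasticity-robust SEs. Two conventions deserve note. First, the
weight is the *inverse SE*, not the usual inverse variance; that is the
definition this analysis family uses, and `weight_scheme =
"inverse_variance"` exposes the conventional alternative. Second, feature
moments are computed over baseline rows (one record per subject), so a
longitudinal study's features describe its enrolled sample. Skewness is the
adjusted Fisher–Pearson sample statistic. Partial prediction curves hold
the other features at reference values (mean age 45 y, SD 7 y, skewness 0,
proportion male 0.5, cross-sectional design) and warn outside the observed
feature range, where the spline extrapolates linearly by construction.
Multiplicity across outcome families is handled by Benjamini–Hochberg
adjustment. Random-effects meta-analysis (τ² heterogeneity) is out of
scope; the model is a fixed-effect weighted regression.

## The synthetic cohort generator

Every stage is exercised on synthetic cohorts, generated from the same mean
structure the models fit:

$$y_{ij} = f(\text{age}_{ij}) + \beta_{\text{sex}}\,\text{sex}_i +
\beta_b b_i + \beta_w w_{ij} + u_i + e_{ij},$$

with a cubic-polynomial age effect on standardized age (smooth
non-linearity a df=2 spline can track), a subject-level covariate component
$b_i$ and visit-level deviation $w_{ij}$ (the observed covariate is their
sum; the baseline deviation is zero so the subject level equals the
baseline value, matching the `X_bl` anchoring), a Gaussian subject
intercept $u_i$ and Gaussian residual $e_{ij}$. Sex is Bernoulli(0.5) by
default; visit gaps are drawn from a configurable distribution and floored
at 0.1 years so visit ages strictly increase. Missingness is applied
uniformly at random to non-baseline visits only, because baseline-anchored
models need a baseline row. The two-wave behavioural variant adds
visit-level measurement noise to the *observed* covariate while the outcome
is driven by the latent components — the structure that produces low
within-subject associations for stable outcomes. The within-subject error
distribution of real behavioural covariates is not documented anywhere
authoritative; Gaussian is assumed.

One master seed governs everything; per-study, per-replicate and
per-bootstrap streams use child seeds from `derive_seeds()`, so any
replicate can be regenerated in isolation and experiments parallelize
reproducibly.

What the generator does *not* emulate: realistic lifespan volume
trajectories, site-by-age interactions, informative missingness, and
imaging measurement pipelines. Passing tests therefore demonstrate the
statistical machinery under its stated assumptions — correct mean model,
exchangeable-like within-subject correlation, missingness at random — not
robustness to the full messiness of consortium MRI data.

A curation rule applies throughout: a table in which fewer than three
subjects have repeated visits is demoted to cross-sectional (baseline rows
only), since so few repeated subjects cannot support a working-correlation
estimate.

## Numerical choices and test scales

* GEE: tolerance 1e-8 on the max coefficient change, 100 iterations max,
  hard failure on non-convergence; working correlation clamped to a valid
  range during iteration.
* Wald statistics: coefficient subsets exactly at the null return
  $T^2 = 0,\ p = 1$ directly, which also handles degenerate zero-variance
  outcomes whose robust covariance is singular.
* Percentile CIs use type-1 (order-statistic) quantiles; probabilities are
  rounded to 10 decimals first because floating-point noise in
  `(1 - level)/2` can otherwise shift a bound by one order statistic.
* The sample-size solver is exact in integer N (bracketing + bisection,
  verified against linear scan).
* Local frequency is computed by exact windowed counting in chunks
  (never approximated by a kernel), so duplicated records each count.

The test suite sizes its simulations for a desk machine: consistency checks
use $n = 10^4$ with tens of replicates, the power calibration uses $10^4$
Monte-Carlo fits at $N = 200$, recovery properties use 200 replicates at
$n = 1000$, and scheme experiments use a few hundred bootstrap replicates.
These sizes were chosen so each property's Monte-Carlo error is several
times smaller than the tolerance it is tested at.

## Known limitations

* Identity-link continuous outcomes only; no survival, logistic or
  count-model effect sizes.
* The site-adjustment stage removes additive site offsets only.
* The CS-RESI bootstrap CI is the contract; no closed-form CI is shipped.
* Weighted resampling targets the covariate distribution; it does not
  implement optimal two-phase or outcome-dependent design solvers, nor
  inverse-probability re-weighting back to population effect sizes.
* Local frequency is exact but quadratic in the number of records per
  chunk; for very large cohorts the weight-construction step dominates.
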