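# bwasdesign

Design optimization for brain-wide association studies (BWAS): robust
standardized effect sizes, targeted-sampling design experiments, power and
replicability calculation, and effect-size meta-regression — with a
synthetic multi-study generator so every stage runs without restricted
consortium data.

BWAS regress brain measures (volumes, cortical thickness, connectivity) on
behavioural and demographic covariates. Their notoriously small
standardized effect sizes are usually attacked with larger samples, but
sample size is only one design lever: the between- and within-subject
variability of the covariate scales the standardized effect size directly
and can be manipulated at design time. This package is for statisticians
and imaging researchers who want to quantify those levers on pilot or
synthetic data before committing to a design.

## What it computes

**RESI.** For a robust Wald statistic
T² = N(β̂−β₀)ᵀΣ̂⁻¹(β̂−β₀) on m parameters, the robust effect size index is

    Ŝ = sqrt( max{0, (T² − m) / N} ),

with N the number of *participants*. Under Cohen's assumptions S = d/2
(medium d = 0.5 ↔ RESI 0.25, large d = 0.8 ↔ RESI 0.4), but unlike d the
RESI stays consistent under unequal variances. Cross-sectional models are
fitted by least squares with sandwich covariance; longitudinal models by
GEE (identity link, exchangeable working correlation, subject-clustered
sandwich). Confidence intervals are subject-level percentile bootstraps.
CS-RESI estimates the effect size the same population would have produced
cross-sectionally, making the two designs comparable.

**Between/within decomposition.** `fit_between_within()` splits a
longitudinal covariate into its baseline value (between-subject effect)
and per-visit change from baseline (within-subject effect), fitted jointly
by GEE — avoiding the variance-weighted averaging that shrinks
single-effect longitudinal estimates when the two effects differ.

**Targeted sampling.** Bell / uniform / U-shaped targets for
between-subject variability and decreasing / uniform / increasing targets
for within-subject change, built by inverse local-frequency weighting plus
target-density rescaling (winsorized for weight assignment only), with a
weighted-bootstrap engine and scheme-experiment runner.

**Power and replicability.** Power from the non-central F distribution
(λ = N·S²), replicability = power², smallest-N solvers, empirical power
from replicate p-values with Wilson intervals.

**Meta-regression.** Study-level effect sizes regressed on design features
(design type, spline terms of mean/SD/skewness of age or proportion male)
with inverse-SE weights and robust SEs, plus partial prediction curves and
Benjamini–Hochberg adjustment.

## Worked example

```r
library(bwasdesign)

cfg <- sim_config(n_subjects = 600, visits_per_subject = 2,
                  beta_between = 0.4, beta_within = 0.1,
                  covariate_within_sd = 0.8, seed = 7)
cohort <- simulate_longitudinal_study(cfg)

fit <- fit_study_model(cohort, y ~ ns(age, df = 2) + sex + x)
resi_for_terms(fit, "x")
#> RESI = 0.3004 (N = 600, m = 1, T2 = 55.129)

fit_between_within(cohort, "x")
#> between/within covariate decomposition (GEE)
#>              effect  estimate  robust_se variance_component
#> 1    between (X_bl) 0.3615369 0.04961858          1.0546650
#> 2 within (X_change) 0.1552094 0.05683875          0.3364351

cs_resi(cohort, y ~ ns(age, df = 2) + sex + x, "x", seed = 1)
#> CS-RESI = 0.2311 (N = 600, m = 1, T2 = 33.364)
```

The single-effect RESI (0.30) hides two different effects: a between-
subject effect of 0.36 and a much weaker within-subject effect of 0.16
(the generator's truth is 0.4 and 0.1). The CS-RESI (0.23) is smaller than
the longitudinal RESI (0.30): collecting a second visit per subject bought
real effect size for this association.

Targeted sampling shows how much design matters at fixed budget — weights
that spread the covariate's baseline distribution (U-shaped) versus
concentrate it (bell):

```r
wt_u <- longitudinal_combination_weights(cohort, target_shape("u_shaped"),
                                         target_shape("uniform"),
                                         covariate = "x")
wt_b <- longitudinal_combination_weights(cohort, target_shape("bell"),
                                         target_shape("uniform"),
                                         covariate = "x")
run_scheme_experiment(cohort, list(u_shaped = wt_u, bell = wt_b),
                      n_grid = c(60, 120), B = 100,
                      formula = y ~ ns(age, df = 2) + sex + x,
                      terms = "x", seed = 3)
#> targeted-sampling experiment: 2 scheme(s) x n in {60, 120}, B = 100
#>    scheme   n    mean_S     ci_low   ci_high n_failed
#>  u_shaped  60 0.4542417 0.16502781 0.9067374        0
#>      bell  60 0.2723307 0.00000000 0.5638010        0
#>  u_shaped 120 0.4888573 0.26422002 0.8133087        0
#>      bell 120 0.2784581 0.06334939 0.5485920        0

n_for_replicability(0.25, 0.8, df_model = 5)
#> [1] 167
```

At n = 120 the U-shaped scheme's mean RESI (0.49) is ~75% larger than the
bell scheme's (0.28) for the same number of scanned participants; an
effect of 0.25 needs 167 participants for 80% replicability in this model.
`run_pipeline()` chains all stages (simulate → site adjustment → fit →
effect sizes → scheme experiment → power summaries → meta-regression) from
one YAML/R config with a hashed output manifest, and
`compare_designs_report()` assembles the per-scheme decision table.

See `vignettes/design-optimization.Rmd` for the models, the weighting
construction, parameter defaults, and what the synthetic generator does
and does not emulate.

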