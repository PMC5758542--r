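# modgain

Does a more modular resting-state brain network at baseline predict who
benefits most from an exercise intervention? `modgain` implements the full
analysis pipeline behind that question for randomized exercise trials in
older adults, together with a synthetic cohort generator that plants known
effects so every stage can be validated by parameter recovery.

The pipeline covers, end to end:

* **Connectome construction** — Pearson correlation of ROI time series,
  Fisher z-transform, and proportional density thresholding into
  unweighted, undirected graphs at costs of 2–10% of all possible
  connections.
* **Network metrics** — Newman–Girvan modularity
  *Q* = Σᵢ (*eᵢᵢ* − *aᵢ*²), where *eᵢᵢ* is the fraction of edges inside
  module *i* and *aᵢ* the fraction of edge endpoints attached to it;
  partitions come from a spectral (leading-eigenvector) maximizer with
  Kernighan–Lin refinement, or from a canonical 13-system assignment.
  Sub-network (association vs. sensory-motor) contributions and weighted
  module segregation (*Z*w − *Z*b)/*Z*w are included.
* **Motion quality control** — Power-convention framewise displacement
  (rotations on a 50 mm sphere) and the standard exclusion rules (more
  than 10% of volumes with FD > 0.5 mm, or maximum absolute displacement
  above 4.0 mm).
* **Behavioral scoring** — 3-SD exclusion then winsorization, standardized
  gain scores (post − pre)/SDpre with direction handling, construct
  composites (vocabulary, speed, memory, executive function), a PCA check
  of the construct structure, and task-switching scoring.
* **Inference** — mixed (split-plot) ANOVA, gain (AN)COVA with per-group
  tests against zero, the moderated regression of EF gain on age, mean FD,
  baseline EF, baseline modularity and a baseline-EF × modularity
  interaction, partial correlations, and bias-corrected and accelerated
  (BCa) bootstrap confidence intervals throughout.
* **Synthetic cohorts** — block-covariance ROI time series whose
  within/between-module contrast tracks a latent per-subject modularity
  target, motion traces with spike contamination, and a 17-test pre/post
  battery with a planted modularity → EF-gain slope moderated by baseline
  EF.

## A worked example

Simulate a 120-subject cohort, assemble the analysis table, and fit the
moderated gain model in the walking group:

```r
library(modgain)

cfg    <- sim_config(n_subjects = 120, seed = 42)
sim    <- simulate_cohort(cfg)
cohort <- assemble_cohort(sim$cohort)

walk <- dplyr::filter(cohort, group == "walk")
fit  <- fit_gain_model(walk, n_boot = 2000, seed = 42)
fit
#> Moderated gain model: R^2 = 0.435, adj. R^2 = 0.317, F(5, 24) = 3.696, p = 0.01272, n = 30
#>                  term estimate  p.value   conf.low conf.high
#> 1         (Intercept) -1.56260  0.12082 -3.431e+00   0.52061
#> 2                 age  0.01666  0.06440  3.553e-04   0.03598
#> 3             mean_fd -0.31781  0.96685 -1.174e+01  13.26771
#> 4            baseline -0.04840  0.47675 -1.993e-01   0.08554
#> 5          modularity  1.43775  0.07376 -1.409e-01   2.89860
#> 6 baseline:modularity -3.90010  0.00145 -5.581e+00  -0.38136
```

The `modularity` row is the slope of EF gain (in pre-test-SD units) per
unit of baseline modularity Q: here 1.44, with a BCa 95% interval from the
2000 case resamples. The negative `baseline:modularity` coefficient says
the modularity–gain relationship is strongest in subjects with lower
baseline EF (this cohort was generated with planted values 1.8 and −2.4,
so both signs and magnitudes are being recovered from a single n = 30
group). `tidy(fit)` and `glance(fit)` return the same information as
tibbles, and `autoplot(fit)` draws the coefficient forest plot.

A covariate-adjusted partial correlation across the whole cohort:

```r
partial_correlation(cohort, "modularity", "ef_gain",
                    c("age", "mean_fd", "ef_baseline"),
                    n_boot = 2000, seed = 42)
#>   estimate  df statistic   p.value conf.low conf.high   n
#> 1    0.358 115      4.11 0.0000758    0.151     0.537 120
```

And the imaging half, from one subject's time series to modularity across
density thresholds:

```r
ts <- simulate_timeseries(cfg, 1)
subject_modularity(ts, costs = c(0.02, 0.06, 0.10),
                   canonical = sim_partition_table(cfg))
#>   cost    source     Q n_modules
#> 1 0.02  spectral 0.734        43
#> 2 0.02 canonical 0.729        13
#> 3 0.06  spectral 0.652        13
#> 4 0.06 canonical 0.647        13
#> 5 0.10  spectral 0.556         8
#> 6 0.10 canonical 0.547        13
```

See `vignettes/modgain-methods.Rmd` for the model, the generator's design,
and every numerical convention.

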