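---
title: "Methods: from resting-state graphs to moderated gain models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from resting-state graphs to moderated gain models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modgain)
```

## The scientific question

Older adults differ widely in how much they benefit from an exercise
intervention. One candidate predictor of that benefit is the *modularity* of
the brain's resting-state functional network at baseline: a brain whose
functional graph decomposes cleanly into segregated modules may be in a
better position to profit from training. `modgain` implements the full
analysis chain needed to ask that question quantitatively — graph
construction from ROI time series, modularity and segregation metrics,
motion quality control, cognitive-battery scoring, and a moderated
regression of executive-function (EF) gain on baseline modularity — plus a
synthetic cohort generator with planted effects so that every stage has a
parameter-recovery test.

## Graph construction

A subject's input is a volumes-by-ROIs matrix of region-averaged,
preprocessed BOLD time series (the emulated acquisition is 180 volumes at
TR = 2 s over 252 ROIs of a 264-region parcellation with cerebellar and
poorly covered regions removed; preprocessing itself — motion correction,
nuisance regression, bandpass filtering — is upstream of this package).

1. `correlation_matrix()` computes all pairwise Pearson correlations.
2. `fisher_z()` applies the variance-stabilizing transform z = atanh(r).
3. `proportional_threshold()` binarizes at a *cost*: the fraction of all
   `n(n-1)/2` node pairs kept as edges. The retained count is exactly
   `floor(cost * M)`; `floor` keeps the realized density at or below the
   nominal cost and makes graphs strictly nested across the standard 2-10%
   ladder. Thresholding acts on signed z-values: at these densities only
   strong positive correlations survive, which matches common practice for
   this parcellation-and-cost recipe; an `absolute = TRUE` switch is
   provided for sensitivity analyses. Ties at the cutoff are broken by
   (row, column) order so results are deterministic; with continuous data
   ties have measure zero.

## Modularity

For a partition of nodes into modules, modularity is

$$Q = \sum_{i=1}^{m} \left( e_{ii} - a_i^2 \right),$$

where \(e_{ii}\) is the fraction of edges joining two nodes inside module
*i* and \(a_i\) the fraction of edge endpoints attached to module *i*.
`modularity_q()` evaluates this directly from edge counts and also returns
the per-module terms \(q_i = e_{ii} - a_i^2\), which are the basis of the
sub-network decomposition below.

`spectral_partition()` maximizes Q by recursive bisection on the leading
eigenvector of the (generalized) modularity matrix, in the Newman spectral
tradition, with three deterministic refinement safeguards:

* after each bisection, a Kernighan–Lin-style sweep flips single nodes
  across the cut while each flip raises Q by more than 1e-10;
* after the recursion finishes, a full-partition Kernighan–Lin pass moves
  every node once per pass to its best alternative module (existing or
  new), accepting the locally best move even when its immediate effect is
  negative and then reverting to the best intermediate state — this repairs
  early bisections that the within-split sweep cannot reach;
* for networks of up to 100 nodes, the same pass is additionally run from
  the all-singletons partition and the better of the two partitions is
  kept. Small dense graphs are where bisection local optima bite hardest,
  and at that size the agglomerative restart is essentially free.

The leading eigenvector is obtained from the dense symmetric eigensolver in
base R. At the scale of this pipeline (at most a few hundred nodes) the
dense solver is exact, deterministic and faster than an iterative method,
which is why it is used rather than a tolerance-controlled power iteration.
A component whose leading eigenvalue is non-positive, or whose sign vector
is degenerate, is declared indivisible; disconnected components are
partitioned independently and isolated nodes become singleton modules. The
`seed` argument of `spectral_partition()` is accepted for interface
stability but the algorithm contains no randomness.

`canonical_partition()` wraps a published fixed assignment of ROIs to 13
functional systems (default mode, fronto-parietal, cingulo-opercular,
salience, dorsal/ventral attention, auditory, visual, memory, two
sensory-motor systems, subcortical, plus an "unassigned" module), so
modularity can be computed under a partition that does not depend on the
subject's own data.

### Sub-network modularity and segregation

`subnetwork_modularity()` reports the contribution of a class of modules
(e.g., association vs. sensory-motor systems) as \(\sum_{i \in \text{class}}
q_i\) evaluated on the whole-brain graph. This decomposition is the only one
that sums exactly to whole-brain Q over all modules (tested); Q of the
induced subgraph is available behind `method = "induced"`. The "unassigned"
canonical module belongs to neither class by default. The choice between
the two definitions is genuinely open in the literature; the additive one
is the default precisely because of its conservation property.

`module_segregation()` works on the *weighted* Fisher-z matrix instead of a
thresholded graph: segregation \(= (Z_w - Z_b)/Z_w\), with \(Z_w\) the mean
z over within-module pairs and \(Z_b\) the mean z over pairs linking a
module in scope to any other module. It is 1 when between-module
connectivity vanishes, 0 when the matrix is homogeneous, and undefined when
\(Z_w = 0\) (an error).

## Motion quality control

`framewise_displacement()` implements the Power convention: the L1 norm of
backward differences of the six rigid-body parameters, rotations converted
to arc length on a 50 mm sphere (0.01 rad contributes 0.5 mm). A
Jenkinson-style RMS variant is available behind `method = "jenkinson"`.
`apply_exclusion()` excludes a subject when *strictly more than* 10% of
volumes have FD > 0.5 mm, or when the maximum absolute displacement
*strictly exceeds* 4.0 mm — both rules follow "more than"/"greater than"
wording, so a subject at exactly the boundary is retained. Maximum absolute
displacement is measured on the translation columns relative to the first
volume, a convention this package fixes explicitly since realignment tools
differ. Rotation units of motion files are likewise never guessed:
`read_motion()` has no default for `rotation_units`.

## Behavioral scoring

Raw test scores are cleaned by a two-pass rule (`clean_scores()`): values
more than 3 SD from the mean are excluded; the mean and SD are recomputed
on the survivors and remaining values beyond 3 SD are winsorized to the
cutoff. The winsorization clamp is iterated to a fixed point — clamping
shrinks the SD, so a single clamp would leave values strictly outside 3 SD
of the *final* statistics and the operation would not be idempotent;
iterating (almost always one or two rounds) makes cleaning a projection,
which is what a data-cleaning step should be. Both comparisons are strict,
so a value at exactly 3 SD is untouched.

Standardized gains are \((\text{post} - \text{pre}) / SD_{\text{pre}}\)
with the pre-test SD pooled across groups, multiplied by a per-test
direction flag (−1 for lower-is-better measures such as an RT switch cost)
so that positive gain always means improvement. Construct composites
average the member tests' baseline z-scores (standardized against the
analyzed sample) and standardized gains over four constructs — vocabulary,
perceptual speed, episodic memory, and EF (six fluid-reasoning tests plus
spatial working memory and task switching). Composites are averaged over a
subject's available member tests, with a completeness column for
filtering, rather than dropped on any missingness.

`pca_check()` verifies the construct structure: PCA on the correlation
matrix of baseline scores, four components retained, oblique (promax)
rotation — a pattern matrix implies an oblique rotation, and cognitive
constructs are expected to correlate, so an orthogonal rotation would be
the wrong default. Each test's dominant component is taken by absolute
loading (a lower-is-better measure loads negatively on its construct).

`task_switching_scores()` derives the local switch cost (mean correct
switch RT minus mean correct non-switch RT) used in intervention analyses,
and a rank-binning score combining accuracy and speed: subjects' RT costs
and accuracy costs are each ranked into decile bins (1 = best) and summed.
The binning recipe is isolated in one function so it can be swapped without
touching anything else.

## The inferential layer

`mixed_anova()` is the classical split-plot decomposition for pre/post by
group, reporting F, p and partial eta-squared per effect; the time effect
in a single-group design reduces to the squared paired t, which is used as
an oracle identity in the tests. `gain_anova()` runs the one-way (AN)COVA
on a composite gain with per-group one-sample tests against zero and
Bonferroni-adjusted pairwise contrasts. Classical (not Welch) F statistics
are used, matching the field's reporting style; a warning is emitted when
group variances differ by more than fourfold.

`fit_gain_model()` is the headline model: OLS of EF gain on age, mean FD,
baseline EF, baseline modularity Q, and a baseline-EF-by-modularity
interaction. The interaction is formed from mean-centered copies of both
variables (a `center = FALSE` switch exists): centering leaves the
interaction coefficient untouched but makes the main effects interpretable
at the sample mean, matching how separate main effects are reported
alongside an interaction. Predictor collinearity is guarded by a condition
number check (error above 1e8). Coefficient intervals are reported two
ways — case-resampling BCa bootstrap (the package's primary flavor, to
match the blanket use of BCa intervals in this literature) and analytic
OLS — because which of the two a published table used is often not
recoverable. A `reduced = TRUE` switch fits the modularity-only model used
as a follow-up when the full model is not significant; it is available for
every group for symmetry.

`partial_correlation()` correlates OLS residuals of x and y on a covariate
set (df = n − #covariates − 2), with one-tailed options for confirmatory
follow-ups, and `bca_ci()` provides the interval machinery: bias correction
z0 from the share of bootstrap replicates below the point estimate, and
acceleration from jackknife skewness,
\(a = \sum (\bar t - t_i)^3 / \big(6 [\sum (\bar t - t_i)^2]^{3/2}\big)\).
With z0 = a = 0 the interval reduces to the percentile interval (tested). A
degenerate bootstrap distribution is an error; a point estimate outside the
bootstrap range clamps z0 with a warning. All bootstrap and simulation
seeds are explicit arguments, so reported intervals are bit-reproducible.

## The synthetic cohort generator

`sim_config()` fixes the emulated study conditions; `simulate_cohort()`
generates them. Design choices worth spelling out:

* **Block-covariance time series.** Each subject's ROI series are i.i.d.
  draws from a zero-mean multivariate normal whose correlation is
  `r_within` inside planted modules and `r_between` across them,
  implemented by the exact factor construction (global factor + module
  factor + noise). The analysis uses only static correlation, so
  autoregressive temporal realism would add nothing the pipeline could
  detect. Defaults `r_within = 0.25`, `r_between = 0.05` give 6%-cost
  graphs with clear but not caricatured modular structure.
* **Latent modularity drives the contrast.** Each subject has a latent
  modularity target (mean 0.45, SD 0.07, the scale of a 6%-cost spectral
  Q); their within-module correlation scales monotonically with it. The
  measured Q of the generated graph therefore carries the planted
  brain-behavior effect *imperfectly*, as in real data. Consequently the
  generator offers `modularity_source = "latent"` — placing the latent
  value itself in the cohort's modularity column — for studies of the
  inferential machinery, where regressing on an attenuated proxy of the
  planted regressor would confound estimator properties with measurement
  attenuation. The imaging path is validated separately (monotonicity of Q
  in the contrast, planted-partition recovery, flat-contrast null).
* **Planted gain model.** EF construct gain = group mean +
  `beta_modularity` × (Q − mean Q) + `beta_interaction` × (centered
  baseline EF) × (Q − mean Q) + noise. Centering the modularity term in
  the generator makes the per-group means interpretable as mean gains at
  cohort-average modularity; it changes nothing about slope recovery.
  Default planted coefficients (1.8 and −2.4) are of the magnitude
  reported for walking interventions in this literature; group mean gains
  (0.16, 0.17, 0.19, 0.03 SD units for the two walking groups, a
  stretching group and a dance group) mirror the pattern of strong gains
  in three groups and none in the fourth. The gain residual SD (0.35) was
  chosen once as a realistic composite-gain dispersion.
* **Battery.** 17 tests load 0.8 on their construct factor (factors
  correlate 0.3); per-test gains add noise (SD 0.15) around the construct
  gain; the switch-cost test is generated and scored lower-is-better.
  Native-unit means/SDs are arbitrary, since standardized scoring removes
  them.
* **Motion.** Random-walk drift (0.02 mm per frame; rotations scaled by
  the 50 mm convention) plus persistent 0.6–1.2 mm translation steps at a
  per-volume spike probability (default 0.02), each registering as exactly
  one FD exceedance of the 0.5 mm screen.
* **Reproducibility.** One master seed; every subject and purpose
  (modularity target, time series, motion, battery) has its own derived
  substream, so any subject's data can be regenerated in isolation. The
  derived seeds are rehashed through the generator itself because the raw
  (seed, subject, stream) lattice is arithmetic and leaks faint
  correlations into neighbouring streams' first draws — faint, but enough
  to distort the type-I error of downstream regressions in large
  simulation studies.

What the generator does *not* emulate: hemodynamics, scanner noise
spectra, physiological confounds, site effects, practice-effect
heterogeneity, or missing-data mechanisms. Passing recovery tests on this
cohort demonstrates that the pipeline's estimators are consistent and its
intervals calibrated under the planted model — not that any particular
real dataset satisfies that model.

## Numerical choices and degenerate inputs

* Symmetry of connectivity matrices is enforced to 1e-12; diagonals are
  excluded everywhere.
* |r| = 1 off-diagonal is an error in `fisher_z()` (infinite z; almost
  always duplicated ROIs).
* A cost yielding zero edges, an edgeless graph in `modularity_q()`, zero
  pooled pre-test SD, Zw = 0 in segregation, and a constant bootstrap
  statistic are all errors, not silent NAs.
* Zero score dispersion in `clean_scores()` returns the input unchanged
  with a warning.
* Refinement move acceptance uses a 1e-10 threshold on delta-Q, so
  floating-point noise cannot flip partitions between runs.

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script run: 200 random graphs (n <=
8) against the brute-force enumeration of all set partitions; 100 planted
4-block graphs (60 nodes); 500 simulated cohorts of n = 120 (plus 500
null cohorts) with 1000 bootstrap resamples each for the moderated-model
recovery study; and 1000 simulations (n = 50, B = 5000, the study's
bootstrap convention) for BCa coverage of a correlation. These sizes keep Monte-Carlo error well inside the
property bounds being checked while completing in minutes on a single
core.

## Known limitations

* The spectral optimizer guarantees near-optimality empirically (checked
  exhaustively at small n), not provably; modularity maximization is
  NP-hard in general.
* Bin-score recipes vary across labs; ours is one defensible reading of
  accuracy-and-RT rank binning, and it is deliberately quarantined in a
  single function.
* BCa intervals at n of order 30 (per-group fits) inherit the method's
  known small-sample undercoverage; the analytic OLS intervals are
  reported alongside for that reason.
* The full imaging path (time series to measured Q) attenuates planted
  brain-behavior slopes by construction; quantifying that attenuation
  against real test-retest data is outside scope.
```{r session}
sessionInfo()
```
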