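---
title: "Meta-analysis of nitrogen recovery efficiency responses to cropland management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of nitrogen recovery efficiency responses to cropland management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuemeta)
```

## The scientific problem

Fertilizer nitrogen recovery efficiency (NUEr) is the share of applied N
that ends up in aboveground crop uptake, in percent. Field experiments
worldwide have compared NUEr under improved management practices — enhanced
efficiency fertilizers (EE), combined mineral/organic fertilization (CF),
organic fertilizer (OF), the 4R fertilizer placements/rates/timings
(RFP/RFR/RFT), residue retention (RES), cover cropping (CC), crop rotation
(ROT), and zero or reduced tillage (ZT/RT) — against conventional controls,
for wheat, maize and rice. `nuemeta` implements the complete inference chain
that turns a compiled corpus of such paired observations into (i)
per-practice effect estimates, (ii) a moderator model describing how effects
depend on site conditions, and (iii) gridded predictions of the achievable
NUEr gain with confidence intervals and area-weighted summaries.

## Effect sizes

Each observation is a control–treatment pair with group means
$X_c, X_t$ (NUEr, %), SDs $s_c, s_t$ and replicate counts $n_c, n_t$. Three
standard effect sizes are supported, each with its analytic sampling
variance:

* **ROM** (log ratio of means): $y = \ln(X_t/X_c)$,
  $v = s_t^2/(n_t X_t^2) + s_c^2/(n_c X_c^2)$; back-transformed to a percent
  change via $(e^y - 1) \times 100$.
* **MD** (raw mean difference): $y = X_t - X_c$, $v = s_t^2/n_t + s_c^2/n_c$,
  in NUEr percentage points.
* **SMD** (standardized mean difference): $y = (X_t - X_c)/SD_p$ with the
  pooled within-group SD
  $SD_p = \sqrt{((n_t-1)s_t^2 + (n_c-1)s_c^2)/(n_t+n_c-2)}$ and
  $v = (n_t+n_c)/(n_t n_c) + y^2/(2(n_t+n_c))$.

The SMD is the plain standardized difference; the Hedges small-sample factor
is available behind `hedges = TRUE` but is off by default so that the
implemented formula matches the definition above exactly.

To compare metrics on a common scale, relative (ROM) and standardized (SMD)
effects are converted to absolute NUEr points using practice-group reference
quantities: the mean control NUEr $\bar X_c$ and the mean pooled SD
$\overline{SD}_p$ of each practice class (`conversion_context()`). The
relative change enters the ROM conversion as a fraction: a 25% relative gain
at $\bar X_c = 32$ is $0.25 \times 32 = 8$ NUEr points, which coincides
exactly with the MD of the same observation — a consistency identity the
test suite checks. Taking "percent times percent" literally would produce
the wrong units, so the fractional reading is the only coherent one.

## Completing incomplete reporting

Primary studies frequently omit dispersions or replicate counts.

* Missing SDs are imputed as
  $SD_i = \overline{CV} \times \bar x_i \times 1.25$, where $\overline{CV}$
  is the mean coefficient of variation over all rows that do report an SD
  and 1.25 inflates the imputed value to penalise non-reporting. By default
  one pooled $\overline{CV}$ is computed over treatment and control arms
  together; this maximises the sample behind the CV and matches the single
  CV used in the rule. Per-arm pooling is available (`pool = "per_arm"`)
  for sensitivity analysis. Imputation is idempotent and flags every
  imputed value.
* Missing replicate counts default to 3, the typical plot-trial design.
  Counts below 2 are rejected outright because every variance formula above
  degenerates there.

Rows with $X_c \le 0$ or $X_t \le 0$ are retained but flagged: the ROM is
undefined for them while MD and SMD are not, so they are excluded from ROM
analyses only. Site covariates are never imputed from coordinates inside
this package; rows lacking them are rejected with a row-indexed diagnostic.

## Pooling published meta-analytic estimates

When several published meta-analyses report an estimate $x_i$ with standard
error $\sigma_i$ for the same practice, `pool_estimates()` combines them by
inverse-variance weighting,
$\bar x = \sum (x_i/\sigma_i^2) / \sum (1/\sigma_i^2)$ and
$\sigma_{\bar x} = 1/\sqrt{\sum 1/\sigma_i^2}$. This is deliberately the
common-effect pool — no between-source variance is added — implemented
literally; when the Cochran $Q$ across sources exceeds its degrees of
freedom a heterogeneity warning tells the user the pooled SE may be
optimistic. Estimates reported under different effect-size metrics are never
pooled together; `pool_by_practice()` refuses mixed metrics with a
diagnostic rather than silently mixing scales.

## The meta-regression model

The core model relates each effect size to moderators:

$$y_i = \beta_0 + \beta_1 x_{i1} + \beta_2 x_{i2} + \beta_3 x_{i1} x_{i2}
+ \dots + u_i + e_i,$$

with $e_i \sim N(0, v_i)$ (known sampling variance) and study-clustered true
effects $u_i$ with a compound-symmetric (CS) covariance: $\mathrm{Var}(u_i)
= \tau^2$ and $\mathrm{Cor}(u_i, u_j) = \rho$ for two observations of the
same study. Moderators are practice indicators (treatment-coded against the
conventional control: mineral fertilizer, conventional tillage,
monoculture, no cover crop, residue removal), crop-type indicators (wheat
is the reference), continuous site covariates (N rate, MAT, MAP, SOC, clay,
pH) centred and scaled to unit variance, a squared N-rate curvature term
(squared on the raw scale first, then scaled as its own variable, so its
coefficient reads as "per SD of N-rate²"), and user-chosen two-way
interactions. Centring before scaling is a deliberate choice: interaction
products of uncentred covariates are numerically unstable and nearly
collinear with their parents, and the stored centre/scale pair makes every
coefficient back-transformable either way. A pairwise-correlation screen
(|r| > 0.8 warns) and an exact rank check run before every fit.

### Estimation

Variance components are estimated by REML (ML optional). Writing
$\mathbf{M}(\tau^2, \rho) = \mathbf{D} + \mathrm{diag}(v)$ with
block-diagonal $\mathbf{D}$, each study block is a diagonal plus a rank-one
matrix, so $\mathbf{M}^{-1}$ and $\log|\mathbf{M}|$ have Sherman–Morrison
closed forms and one likelihood evaluation costs $O(kp)$ — the package
never forms a dense $k \times k$ covariance. $\hat\beta$ is the GLS solution
at the optimum with $\mathrm{Cov}(\hat\beta) = (\mathbf{X}^\top
\mathbf{M}^{-1}\mathbf{X})^{-1}$.

Numerical choices, all deterministic:

* parametrisation $(\log\tau^2, \mathrm{logit}\,\rho)$ with
  $\rho \in [0, 1)$ — negative within-study correlation of true effects has
  no sensible reading for study clustering;
* a fixed 5 × 5 start grid (data-anchored $\tau^2$ scale × five $\rho$
  values), local `nlminb` refinement from the best starts, relative
  tolerance $10^{-8}$, at most 500 iterations per start;
* the $\tau^2 = 0$ boundary is always evaluated and wins ties;
* with one effect per study $\rho$ is unidentifiable: the model reduces
  exactly to a standard random-effects fit in $\tau^2$ and the reported
  $\rho$ is flagged `rho_identifiable = FALSE`;
* constraining $\tau^2 = 0$ reproduces inverse-variance weighted least
  squares exactly, which ties the meta-regression back to
  `pool_estimates()` (tested to $10^{-10}$).

The test suite validates the optimiser against a deliberately naive dense
grid search of the restricted likelihood, and against an independent
multilevel implementation on a shared instance.

### Inference and model comparison

* `wald_test()` gives the omnibus chi-square ("linear contrast ANOVA") for
  any coefficient subset. p-values are chi-square tail probabilities with no
  multiplicity adjustment.
* `qe_test()` computes the residual-heterogeneity statistic $Q_E$ at the
  fixed-effects weighted fit, on $k - p$ degrees of freedom.
* `information_criteria()` reports AIC with $q = p + 2$ parameters
  ($p + 1$ when $\rho$ is unidentifiable). Both an ML-based and a REML-based
  value are reported: REML likelihoods are not comparable across different
  fixed-effects structures, so cross-moderator comparison should use the ML
  value, but both are exposed for traceability to software that reports
  REML-based criteria.
* `pseudo_r2()` is McFadden's $1 - \ell_{model}/\ell_{null}$ on full (ML)
  likelihoods against the intercept-only model with the same random-effects
  structure.

## Scenarios and upscaling

A fitted MD-metric model predicts the absolute NUEr change of a management
scenario at any site. `encode_scenario()` builds the design row for a grid
cell and crop — practice indicators from the scenario, the crop indicator,
cell covariates scaled by the stored training-scale parameters, and all
interaction products. Bundles are encoded jointly in one row (all bundle
indicators 1 simultaneously, interactions active), not as a sum of
separately predicted singles: the linear predictor is a single function and
joint encoding is what it means to apply practices together.

`predict_grid()` forms, per cell, the crop-share-weighted contrast vector
between scenario and baseline rows and evaluates $\Delta = \mathbf{d}^\top
\hat\beta$, $se = \sqrt{\mathbf{d}^\top \mathrm{Cov}(\hat\beta)\mathbf{d}}$,
with 95% bounds at $\pm 1.96\,se$ — fixed-effects uncertainty only, the
convention for mapping the uncertainty of the estimated mean response;
`interval = "prediction"` adds $\tau^2$ for the spread of individual sites.
Cells whose covariates fall outside the calibration range recorded at fit
time trigger an extrapolation warning (with the cell ids) but are still
predicted; clipping is deliberately not applied by default. Baseline
self-contrast is identically zero, and the MD metric is recommended for
upscaling because its scale is NUEr percentage points; other metrics
predict on their own scale with a warning. `summarize_grid()` returns
cropland-area-weighted means of the per-cell change and its CI bounds,
globally and per region, renormalising weights over available cells.

## The synthetic-data generator

`simulate_observations()` emulates the statistical structure the model
assumes, with known ground truth, so every stage is testable without any
external download:

* study effects follow the CS structure exactly (a shared
  $N(0, \rho\tau^2)$ study component plus idiosyncratic
  $N(0, (1-\rho)\tau^2)$ deviations);
* covariates are drawn within the observed field ranges of the compiled
  corpus (MAT −0.6–29 °C, MAP 45–2330 mm yr⁻¹, SOC 2.7–80 g kg⁻¹, pH
  4.5–8.5, clay 8.8–53%), control NUEr within 20–60%, replicate counts
  3–6, arm SDs 3–8 NUEr points;
* 20% of rows withhold their SDs by default, exercising the CV imputation
  the way incomplete reporting does in the real corpus;
* 30% of treatment arms co-apply a second practice (`"A+B"`). Multi-practice
  arms occur throughout field corpora, and without them every arm carries
  exactly one practice, making the indicator columns sum to the intercept —
  an exactly collinear design;
* for the MD metric the emitted arm means reproduce the target effect plus
  sampling noise whose variance equals the analytic formula exactly; for
  ROM and SMD the arm means are derived from the target ratio or
  standardized difference, with normal noise on the arm-mean scale (a close
  approximation at realistic noise levels, checked by correlation with the
  truth in tests).

Ground truth is defined on the sample-scaled covariate scale: true effects
are $\mathbf{X}\beta$ with $\mathbf{X}$ built using the same scaling a
downstream fit recomputes from the generated table, so recovery experiments
compare identical parametrisations rather than confounding recovery with
scaling re-estimation.

What the generator does **not** emulate: the geographic clustering of real
study corpora, correlated covariates (available optionally only through the
user supplying pre-correlated ranges), non-normal effect distributions,
publication bias, and reporting artefacts beyond missing SDs. Passing
recovery tests therefore demonstrate that the estimator is correct under
its own assumptions, not that those assumptions hold for any particular
field corpus.

### Calibration experiment

`recovery_experiment()` repeats simulate-and-fit and records per-coefficient
95% Wald CI coverage and heterogeneity bias. The package's acceptance
checks run it at 30 studies × 5 observations, $\tau^2 = 4$, $\rho = 0.5$,
with a 13-term moderator set including one interaction, with full SD
reporting — the experiment measures estimator calibration, so reporting
noise is kept out of it (the pipeline default keeps the 20% drop). At 2000
replicates every coefficient's coverage sits within 0.93–0.97 and the
relative bias of $\hat\tau^2$ is a few percent. The oracle-equivalence
check uses 20 instances of 6 studies × 3 effects against a dense
likelihood grid; these sizes keep the default test run to roughly a minute
on one core while leaving the Monte Carlo error small relative to the bands
being checked.

## Known limitations

* The CS structure is the only random-effects covariance offered; no
  unstructured, heteroscedastic or autoregressive alternatives, no robust
  (sandwich) standard errors, and no publication-bias diagnostics.
* Grid input is tabular (CSV); the package does not read rasters or
  download climate/soil/land-use layers, so reproducing a full global map
  requires the user to supply pre-extracted cell tables.
* Variance-component estimates from a single corpus of ~30 studies are
  noisy, and imputed SDs distort $v_i$; point estimates of $\tau^2$ and
  $\rho$ should be read with their uncertainty in mind even though
  coefficient CIs remain well calibrated.
* Wald intervals use the normal critical value 1.96; no small-sample
  t-type adjustment is applied.
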