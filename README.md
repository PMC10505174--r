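# nuemeta

Meta-analysis of fertilizer **nitrogen recovery efficiency (NUEr)**
responses to cropland management practices, and upscaling of the fitted
model over covariate grids.

NUEr is the fertilizer-induced increase in aboveground crop N uptake
divided by the N applied, in percent. Field experiments worldwide compare
NUEr under improved practices — enhanced-efficiency fertilizers (EE),
combined mineral/organic fertilization (CF), organic fertilizer (OF), the
4R placements/rates/timings (RFP/RFR/RFT), residue retention (RES), cover
cropping (CC), crop rotation (ROT), zero/reduced tillage (ZT/RT) — against
conventional controls for wheat, maize and rice. `nuemeta` turns a corpus
of such paired observations into per-practice effects, a site-condition
moderator model, and gridded predictions of the achievable NUEr gain.

## What the package computes

For each control–treatment pair with means $X_c, X_t$, SDs $s_c, s_t$ and
replicates $n_c, n_t$ it supports three effect sizes with analytic
sampling variances:

* log ratio of means: $y = \ln(X_t/X_c)$,
  $v = s_t^2/(n_t X_t^2) + s_c^2/(n_c X_c^2)$;
* raw mean difference (NUEr points): $y = X_t - X_c$,
  $v = s_t^2/n_t + s_c^2/n_c$;
* standardized mean difference: $y = (X_t - X_c)/SD_p$,
  $v = (n_t+n_c)/(n_t n_c) + y^2/(2(n_t+n_c))$.

Missing SDs are imputed from the mean coefficient of variation
($SD = \overline{CV} \times \bar x \times 1.25$), missing replicate counts
default to 3. Published meta-analytic estimates are pooled by
inverse-variance weighting. The core model is the mixed-effects
meta-regression

$$y_i = \mathbf{x}_i^\top \boldsymbol\beta + u_i + e_i, \qquad
e_i \sim N(0, v_i),$$

with compound-symmetric study random effects
($\mathrm{Var}(u_i) = \tau^2$, within-study correlation $\rho$), estimated
by REML with a deterministic multi-start optimiser; moderators are practice
and crop indicators plus unit-variance-scaled site covariates (N rate and
its square, MAT, MAP, SOC, clay, pH) and two-way interactions. Fitted
models predict management scenarios over covariate grids with
fixed-effects 95% confidence intervals ($\pm 1.96\,se$) and
cropland-area-weighted summaries. A synthetic-data generator with known
ground truth backs parameter-recovery experiments.

## Worked example

```r
library(nuemeta)

cfg <- nue_sim_config(n_studies = 30, obs_per_study = 5, seed = 101)
sim <- simulate_observations(cfg)     # paired observations + known truth
fit <- nue_meta_model(sim$observations, cfg$spec)
summary(fit)
```

```
Multilevel meta-regression (REML, compound-symmetric study random effects)
k = 150 effects in 30 studies; p = 13 coefficients
tau^2 = 7.1365; rho = 0.5049

Coefficient table:
           estimate     se     z        p sig
intercept    5.1947 1.2221  4.25 2.13e-05 ***
EE           8.4154 0.9925  8.48 2.27e-17 ***
RFR          8.9065 1.0140  8.78 1.58e-18 ***
CC           5.8611 1.0358  5.66 1.52e-08 ***
crop_maize   2.1670 0.9584  2.26 2.38e-02 *
crop_rice   -0.5209 0.8629 -0.60 5.46e-01
n_rate      -1.8681 0.3964 -4.71 2.44e-06 ***
mat          0.1832 0.4018  0.46 6.48e-01
map          0.9223 0.3694  2.50 1.25e-02 *
soc          1.2092 0.3725  3.25 1.17e-03 **
clay        -0.6560 0.3802 -1.73 8.44e-02
ph           1.2771 0.3633  3.52 4.38e-04 ***
n_rate:soc   1.7065 0.3642  4.69 2.79e-06 ***

Q_E = 204.61 on 137 df (p = 0.000161)
logLik (REML) = -428.640; logLik (ML) = -432.049; AIC (ML) = 894.10; AIC (REML) = 887.28
```

The coefficients are on the mean-difference scale: applying the right
fertilizer rate (RFR) raises NUEr by about 8.9 percentage points at
reference conditions, effects decline with higher N application rates
(−1.9 points per SD of N rate) and improve on soils richer in organic
carbon, with a positive N-rate × SOC interaction. `tau^2` is the
between-effect heterogeneity left after the moderators; `rho` the
correlation of effects within one study. Q_E tests whether residual
variability exceeds sampling noise.

Upscaling a practice bundle over a (here synthetic) covariate grid:

```r
grid <- simulate_grid(50, cfg)
bundle <- nue_scenario("nutrient+crop", c("EE", "RFR", "CC"))
pred <- predict_grid(fit, grid, bundle)   # vs conventional baseline
summarize_grid(pred, grid)
```

```
  region delta_nuer_mean   ci_low  ci_high n_cells  weight
1 global        23.18303 18.09568 28.27039      50 28.1327
```

i.e. jointly adopting the three practices raises NUEr by ~23 percentage
points on average over this grid (95% CI 18–28), area-weighted by cropland
per cell. Real applications replace the synthetic table and grid with a
compiled observation CSV (`read_observations()`) and a pre-extracted
0.5° covariate grid; `run_pipeline()` drives the whole chain from one YAML
configuration and writes a hashed manifest.

See the vignette in `vignettes/nue-meta-analysis.Rmd` for the model,
estimation details, and the generator's scope.

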