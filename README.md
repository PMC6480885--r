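# temort

Tensor-product quasi-Poisson models for estimating the health effects of
multiple, strongly correlated air pollutants on daily mortality.

## The problem

Urban PM10, NO2 and SO2 concentrations move together (pairwise Spearman
correlations of 0.6–0.85 are typical). Single-pollutant time-series models
let each coefficient absorb part of the co-pollutants' effects, so summed
single-pollutant excess risks overstate the joint effect of the mixture;
joint linear models suffer collinearity — inflated variances and unstable,
even sign-reversed, per-pollutant estimates. `temort` implements a
penalized **tensor-product smooth** of the three concentrations inside a
quasi-Poisson regression, alongside the three conventional competitors,
so the approaches can be compared on data with a known truth.

## The model

For daily death counts with E(Y_t) = μ_t and Var(Y_t) = φ μ_t:

```
log μ_t = α + ns(TempMA14_t; 3) + ns(RH_t; 3) + ns(Pressure_t; 3)
        + ns(t; 7/year) + DOW_t + Holiday_t + te(PM10_t, NO2_t, SO2_t)
```

where pollutants enter as 3-day moving averages (lag 0–2) and
`te(·,·,·) = Σ_i Σ_l Σ_k v_ilk φ_i(PM10) φ_l(SO2) η_k(NO2)` is a
tensor-product smooth built from cubic regression spline marginal bases
combined by Kronecker products. Coefficients are estimated by penalized
iteratively re-weighted least squares maximizing the quasi-likelihood
minus one roughness penalty per margin, `Σ_m λ_m ∫ (∂²f/∂x_m²)²`, with
smoothing parameters λ selected by generalized cross-validation
(GCV = n·Pearson/(n−edf)²). Effects are rate ratios `RR = exp(teᵀν̂)`
between two exposure profiles with delta-method standard errors
`√(teᵀ Σ̂ te)`, reported as excess risk `ER = (RR−1)·100%` for the default
IQR (25th→75th percentile) contrast. Competing specifications: Model I
(single pollutant, linear), Model II (three pollutants, linear), Model III
(Model II + pairwise products), Model IV (the tensor smooth).

Because no registry mortality series is distributable, the package ships a
synthetic-data generator with the same statistical structure (log-normal
pollutants under a Gaussian copula hitting Spearman targets 0.83/0.60/0.65,
shared annual seasonality, overdispersed counts, known true log-rate
surface), so every estimator is validated by parameter recovery.

## Worked example

```r
library(temort)

cfg <- simulation_config()                       # 2,922 days, phi = 1.5
dat <- simulate_daily_data(cfg, seed = 1, n_missing = 40)

des <- build_model(dat, model_spec("IV"))        # 5x5x5 tensor smooth
fit <- gcv_select(des)$fit                       # GCV-selected lambdas
iqr_effect(fit)                                  # combined IQR contrast
#> Model IV  RR = 1.0335 (1.0189-1.0484)  ER = 3.35% (1.89-4.84%)

# true combined ER implied by the generator's slopes on this dataset:
(exp(sum(cfg$true_effect$slopes *
         des$increments[c("pm10", "no2", "so2")])) - 1) * 100
#> [1] 2.957403
```

The full comparison (driver `analysis/02_fit_models.R`, seed 20260919)
prints:

```
Combined three-pollutant effects:  I=5.74%  II=2.42%  III=2.51%  IV=2.10%
Model IV diagnostics: edf = 80.9  dispersion = 1.491  lambdas = 104000/20100/1e+06
```

The single-pollutant model's summed excess risk (5.74%) far exceeds every
multi-pollutant combined estimate (2.1–2.5%, against a true 2.9% on this
draw) — the signature of collinearity the tensor model is designed to
avoid — while the multi-pollutant linear models pay with per-pollutant
confidence intervals two to three times wider than Model I's.

## Analysis workflow

The numbered drivers under `analysis/` reproduce the study end to end,
writing tables under `results/`:

1. `01_simulate.R` — generate the synthetic daily series and summaries;
2. `02_fit_models.R` — fit Models I–IV, write the comparison table, fit
   logs, Model IV rate-ratio surfaces and exposure-response curves;
3. `03_recovery_study.R` — replicate-world bias/coverage study;
4. `04_sensitivity_stratified.R` — lag 0–1 vs 0–2 sensitivity and
   stratified (subgroup) analyses.

## Package layout

* `R/sim-data.R` — synthetic-data generator (exposures, counts, missing
  injection, CSV schema);
* `R/splines.R` — natural cubic confounder bases; cubic marginal bases
  with exact curvature penalties; tensor rows, expanded penalties,
  centering, plain-text serialization;
* `R/design.R` — lagged exposures, confounder block, model matrices and
  penalties for Models I–IV;
* `R/gam-fit.R` — penalized IRLS, Pearson dispersion, coefficient
  covariance (sandwich/posterior), GCV selection;
* `R/effects.R` — rate ratios, excess risks, delta-method CIs, surfaces
  and exposure-response curves;
* `R/pipeline.R` — orchestration: full runs, stratified analyses, lag
  sensitivity;
* `vignettes/tensor-product-quasipoisson.Rmd` — the methods vignette.
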