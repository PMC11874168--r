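# funqee

Functional and quantile mixed-effects models for school-day energy
expenditure (SDEE) and body weight status.

## What problem this solves, and for whom

Wearable accelerometers in school-based obesity interventions record
energy expenditure minute-by-minute; summarized to hourly means, each
student contributes a *curve* of calories/minute across the school day.
Standard practice collapses that curve to its overall mean and regresses
log(BMI) on it with a linear mixed model — which answers the question only
for children near the average BMI, and says nothing about *when* during
the day activity matters. funqee is for biostatisticians and physical
activity researchers analyzing such cluster-randomized trials (schools as
clusters) who want both axes back:

* time-of-day resolution, via scalar-on-function regression,
  `log(BMI) = b0 + INT b1(t) Z(t) dt + covariates + school effect`, with
  `b1(t)` expanded in B-splines and the curve reduced to integrated
  scores `Z_g = INT Z(t) c_g(t) dt`;
* distributional resolution, via linear quantile mixed models built on
  the asymmetric-Laplace working likelihood, with the school random
  intercept integrated out of each cluster's likelihood — in closed form
  (the summed check loss is piecewise linear in the intercept, so each
  piece is an exp-linear times Gaussian integral).

Four model families result: **LMEM** and **QMEM** (scalar mean-SDEE
exposure), **FMEM** and **FQMEM** (functional exposure, per-quantile
coefficient curves `b_tau(t)`), all with the spline dimension G chosen by
AIC over 4–7 and inference from a subject-level bootstrap stratified by
school (pointwise percentile bands for the coefficient curve, bootstrap
SEs and normal p-values for covariates).

Because the motivating dataset is restricted, the package includes a
calibrated synthetic-data generator (`simulation_truth()`,
`simulate_study()`) whose defaults reproduce the published study's shape:
n = 256 students in 3 schools, 30 hourly SDEE means averaging 1.32 (sd
0.32) cal/min, BMI 17.40 (2.98) kg/m², school ICC 0.10, and known ground
truth for every parameter — so all estimators are testable end to end.

## Worked example

```r
library(funqee)

study <- simulate_study(simulation_truth(seed = 1))
#> <sdee_study> 256 subjects, 3 schools, 30-point SDEE grid (simulated, truth attached)

d <- build_design(study, "mean")          # scalar-exposure design
fit_lmem(d$y, d$X, d$cluster)
#> <sdee_lmem> ML fit, n = 256, logLik = 210.134, AIC = -404.269
#>         term  estimate       se       z          p
#>  (Intercept)  2.463538 0.071178 34.6110 1.725e-262
#>    mean_sdee  0.378858 0.019583 19.3460  2.204e-83
#>          age -0.001936 0.008209 -0.2359  8.135e-01
#>          sex -0.038576 0.013437 -2.8708  4.094e-03
#>         race -0.007628 0.014546 -0.5244  6.000e-01
#>         desk -0.055587 0.013475 -4.1251  3.705e-05
#> Random effects: school var 0.000270, residual var 0.011191 (ICC 0.024)

sel <- select_G_by_aic(study, "fmem", G_range = 4:7)
sel$aic_table
#>   G       aic converged error
#> 1 4 -400.9942      TRUE  <NA>
#> 2 5 -399.6444      TRUE  <NA>
#> 3 6 -397.7906      TRUE  <NA>
#> 4 7 -395.9890      TRUE  <NA>

band <- bootstrap_functional_inference(
  study, function(s) fit_fmem(s, G = sel$G), B = 200, seed = 2)
band
#> <sdee_band> 95% pointwise band from 200/200 replicates (nonparametric)
#> windows where the band excludes zero:
#>  start_index end_index   t_start     t_end direction
#>            3         8 0.1000000 0.2666667  positive
#>           25        30 0.8333333 1.0000000  positive
```

Reading the output: the scalar model finds higher mean SDEE associated
with higher log(BMI) (est. 0.379 — energy expenditure scales with body
mass), boys and stand-biased desks associated with lower log(BMI), and a
small school variance share. The functional band then localizes the
association in wear time: here the 95% pointwise band excludes zero from
roughly the 3rd–8th hour-of-wear (t = 0.10–0.27) — in this simulated
draw the true coefficient is `0.366 + 0.2 sin(2*pi*t)`, largest exactly in
that morning window.

The full four-model report (1 LMEM + 6 QMEM + 1 FMEM + 6 FQMEM, with
per-quantile basis selection and bootstraps) is one call:

```r
report <- run_full_analysis(analysis_config(B = 100, seed = 7,
                                            out_dir = "report"))
```

which writes `descriptives.csv`, `lmem.csv`, `qmem.csv`,
`fmem_band.csv`, `fqmem_band.csv`, `aic_selection.csv`,
`run_metadata.json`, … — byte-identical for the same seed. A command-line
wrapper lives at `inst/cli/funqee.R`
(`simulate` / `analyze` / `recover` subcommands).

## Documentation

The methods vignette (`vignettes/funqee-methods.Rmd`) documents the model
equations and assumptions, the exact closed-form marginal likelihood for
the quantile engine (and why adaptive Gauss–Hermite quadrature was
rejected as the default), the bootstrap scheme, every tunable parameter
with units and defaults, what the synthetic generator does and does not
emulate, and the package's numerical tolerances.
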