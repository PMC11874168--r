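---
title: "Models and methods behind funqee"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind funqee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funqee)
```

## The problem

Wearable devices in school-based obesity interventions produce dense
energy-expenditure (EE) records — calories per minute across the school
day, for every student, over a week. The analytic question is how these
school-day EE (SDEE) patterns relate to body weight status, measured as
log(BMI), in a cluster-randomized trial where classrooms within a handful
of schools were assigned stand-biased or traditional desks. Summarizing
each student's curve by its overall mean answers that question only at the
mean of the BMI distribution and only for the average school-day: it
cannot say *when* during the day activity matters, or whether effects
differ for children in the tails of the BMI distribution, where overweight
and obesity are defined.

funqee implements four model families that differ along exactly those two
axes. All share a school-level random intercept $b_j \sim N(0,\sigma_j^2)$
for the clustering induced by the design, and all adjust for age, sex
(boy vs girl), race (white vs non-white) and desk assignment (stand-biased
vs traditional):

* **LMEM** — Gaussian linear mixed model,
  $Y_{ij} = \beta_0 + \sum_k \beta_{1k} X_{ijk} + b_j + \varepsilon_{ij}$,
  with the overall mean SDEE among the $X$'s.
* **QMEM** — linear quantile mixed model for
  $Q_\tau(Y_{ij})$, same covariates, fitted at
  $\tau \in \{0.10, 0.25, 0.50, 0.85, 0.95, 0.99\}$.
* **FMEM** — scalar-on-function regression,
  $Y_{ij} = \beta_0 + \int_0^1 \beta_1(t) Z_{ij}(t)\,dt +
  \sum_k \beta_{2k} X_{ijk} + b_j + \varepsilon_{ij}$, where $Z_{ij}(t)$
  is the SDEE curve on wear time rescaled to $[0,1]$.
* **FQMEM** — the functional term inside the quantile mixed model,
  giving a coefficient curve $\beta_\tau(t)$ per quantile level.

## Spline reparameterization of the functional term

The coefficient curve is expanded in $G$ known B-spline basis functions,
$\beta_1(t) \approx \sum_{g=1}^G \gamma_g c_g(t)$, which turns the
integral into a finite design: each curve is reduced to scores
$Z_{ijg} = \int_0^1 Z_{ij}(t)\, c_g(t)\,dt$, and the functional model
becomes an ordinary mixed model on $[Z_{ij1}, \dots, Z_{ijG}]$ plus the
scalar covariates. After fitting, the curve is reconstructed as
$\hat\beta(t) = \sum_g \hat\gamma_g c_g(t)$.

Design choices where the method leaves room:

* **Basis dialect.** We use the full clamped (open knot vector) B-spline
  basis, which is nonnegative, locally supported, and sums to one at every
  $t$. The partition-of-unity property gives clean invariants (a constant
  curve has scores summing to that constant; constant $\gamma$ gives a
  flat coefficient curve) and the model intercept stays identified
  because the basis enters only through integrated scores of non-constant
  curves. With $G = 4$ and cubic degree the basis is exactly the
  Bernstein polynomials, which the tests exploit as closed forms.
* **Knots and degree.** Interior knots are equally spaced on $[0,1]$ —
  the observation grid is equally spaced, so quantile-based placement
  would coincide — and the degree defaults to cubic, the standard choice
  for smooth diurnal effects. Both are configurable.
* **Quadrature.** The curve is observed as $m = 30$ hourly means, hour
  $k$ sitting at $t_k = k/m$ with rectangle weights $1/m$ (each hourly
  mean represents a width-$1/m$ slice of the day). A trapezoid rule is
  available on the grid constructor. The rectangle rule has $O(1/m)$
  error; the tests verify the error roughly halves from $m=30$ to $m=60$.
* **Choosing $G$.** The basis dimension is selected by AIC over
  candidates 4–7 (per quantile level for the FQMEM, since different
  quantiles may need different smoothness), ties resolved toward the
  smaller $G$. AIC uses the maximized (working) likelihood with parameter
  count = fixed effects + 2 scale parameters.

## The Gaussian engine

`fit_lmem()` maximizes the (restricted) likelihood of the single random
intercept model by profiling: for a fixed variance ratio
$\lambda = \sigma_j^2/\sigma^2$, the GLS coefficients and $\sigma^2$ have
closed forms through per-cluster sufficient statistics (cluster
cross-products and sums), so one profile evaluation costs $O(Jp^2)$
regardless of $n$ and the whole fit is a bounded 1-D search over
$\log\lambda$ (plus explicit checks of the $\lambda = 0$ boundary and the
ANOVA moment estimator as candidates — the returned optimum always
dominates the ANOVA starting point). ML is the default because the AIC
comparisons across model families require it; REML is available and, for
balanced one-way layouts, reproduces the closed-form ANOVA estimators
exactly, which the tests assert. Standard errors come from the inverse
GLS information and p-values are Wald-z: with as few as three clusters,
denominator degree-of-freedom corrections are not meaningfully defined,
and the bootstrap covers inference for the functional fits anyway.

A numerical note: the profile search resolves $\log\lambda$ to roughly
square-root machine precision, which bounds reproducibility of
shift-invariance identities at about $10^{-8}$ on the coefficients —
exact in the algebra, and tested at that tolerance.

## The quantile engine

The QMEM places the asymmetric Laplace (ALD) working likelihood
$\log f(y) = \log\{\tau(1-\tau)/\sigma\} - \rho_\tau((y-\mu)/\sigma)$
around the linear quantile predictor and integrates a Gaussian random
intercept out of each cluster's likelihood:
$$\ell_j = \log \int \prod_i f_{ALD}\!\big(y_{ij};\, x_{ij}'\beta + b\big)\,
  \phi(b; 0, \sigma_b^2)\, db .$$

**Exact integration instead of quadrature.** The conventional route for
this integral is (adaptive) Gauss–Hermite quadrature. We implemented it
(`method = "agh"`) and found it wanting at exactly the scales this design
produces: with ~85 students per school the cluster integrand is a sharply
peaked, *kinked* exponential (the summed check loss is piecewise linear in
$b$), and Gauss–Hermite error decays slowly and non-monotonically for
kinked integrands — changes in the third decimal of the log-likelihood
between 11 and 21 nodes. But piecewise linearity is also the cure: between
consecutive sorted residuals the integrand is $e^{A + Sb}\phi(b)$, which
integrates in closed form to a difference of normal CDFs. The default
`method = "exact"` sums these $n_j + 1$ pieces per cluster in log space
(stable tail-aware CDF differences), making the marginal likelihood exact
to machine precision and, incidentally, as fast as quadrature. The AGH
route is retained and tested as an independent check that converges to
the exact value. Degenerate mixing ($\sigma_b = 0$) short-circuits to the
independent ALD sum.

**Optimization.** The marginal is continuously differentiable in $\beta$
(integration smooths the check-loss kinks), so a BFGS descent from a warm
start — OLS slopes with the intercept shifted to the $\tau$-quantile of
the OLS residuals, $\sigma_b$ started from the Gaussian fit — is followed
by a Nelder–Mead polish whose convergence flag we trust near the optimum.
Scale parameters live on the log scale and are clamped to ±12 log-units
around the response sd: far outside that window the closed form loses
digits to cancellation, and no maximizer lives there. For intercept-only
models the engine reproduces the sorted-sample quantile to within one
inter-observation gap, the fitted intercepts are monotone in $\tau$, and
shifting the response shifts only the intercept (tested at $10^{-6}$ with
a tightened tolerance).

**Tail guard.** At $\tau = 0.99$ with $n = 256$ only ~2.6 observations
are expected beyond the quantile; such fits are produced but carry a
recorded warning, mirroring the general caution that tail quantile
regression needs large samples.

## Bootstrap inference

Because the spline scores are correlated, model-based standard errors for
$\hat\gamma$ understate the uncertainty of the reconstructed curve. All
functional (and quantile) inference therefore uses a nonparametric
bootstrap of whole subjects — the independent sampling unit — resampled
**with replacement, stratified by school**, so every replicate preserves
the original cluster sizes. Each replicate re-runs the entire fitting
pipeline; the pointwise band at level $1-\alpha$ is the $\alpha/2$ and
$1-\alpha/2$ percentile of the replicate curves at each grid point, and
covariate effects get bootstrap SEs (sd across replicates) with two-sided
normal p-values. Replicates whose fit does not converge are dropped;
losing more than 10% is recorded as a warning in the band metadata.
Windows where the band excludes zero are reported as maximal runs of
consecutive grid points.

A `scheme = "permutation"` flag resamples *without* replacement within
schools. That reproduces the original dataset exactly and collapses the
band to zero width — it exists deliberately, to document why the
with-replacement scheme is the operative reading of a "nonparametric
bootstrap" here.

## The synthetic-data generator

No public version of the motivating dataset exists, so the package ships
a generator whose defaults *are* the published study conditions, fixed
once:

| parameter | default | rationale |
|---|---|---|
| $n$, schools, $m$ | 256, 3, 30 | analytic sample shape |
| mean / sd of per-subject mean SDEE | 1.32 / 0.32 cal/min | descriptive table |
| BMI mean / sd | 17.40 / 2.98 kg/m² | descriptive table |
| age mean / sd | 7.86 / 0.80 y | descriptive table (see note) |
| desk / sex / race proportions | 150/256, 133/256, 176/256 | descriptive table |
| ICC | 0.10 | reported intraclass correlation |
| covariate effects (age, boy, white, desk) | −0.002, −0.045, −0.017, −0.049 | reported scalar-model estimates |
| $\beta_1(t)$ | $0.366 + 0.2\sin(2\pi t)$ | smooth, integrates to the reported scalar SDEE slope |

The study's descriptives report age two ways (7.86 (0.80) in the table,
7.73 (0.74) in the text); the table is used.

Curves are generated as $A_i\,\mu(t) + e_{ik}$: a smooth bimodal diurnal
template $\mu$ (morning and afternoon activity bumps, rescaled to mean
1.32 cal/min), a subject-level lognormal amplitude with mean 1, and
hourly Gaussian noise (sd 0.25 cal/min), floored at 0.05 cal/min. The
amplitude variance is solved so the per-subject mean SDEE has sd exactly
0.32. The outcome is generated on the log scale from the functional model
equation and exponentiated; the school and residual variances are solved
at truth-construction time so that the *marginal* sd of BMI is ≈ 2.98
after accounting for the variance the covariates and the functional term
contribute, split by the target ICC. This is closed-form moment
accounting, not tuning — nothing is adjusted after looking at test
outcomes.

What the generator does **not** emulate: minute-level device records,
wear-time gaps and non-adherence, multi-semester longitudinal structure,
teacher-within-school clustering, or heavy-tailed BMI errors (outcomes
are conditionally Gaussian). A green recovery test therefore establishes
that the estimators recover the truth under the stated world — clustered,
moment-calibrated, smooth diurnal curves — not that they are robust to
device artifacts.

## Numerical choices and degenerate inputs

* Quantile set defaults to {0.10, 0.25, 0.50, 0.85, 0.95, 0.99}; basis
  candidates to 4–7; bootstrap to B = 1000 at level 0.95.
* LMEM profile: search on $\log\lambda \in [-25, 15]$, tolerance 1e-10,
  boundary $\lambda = 0$ checked explicitly.
* QMEM: Nelder–Mead reltol 1e-10, at least $500 \times$ (number of
  parameters) evaluations, one restart on non-convergence; deterministic
  given the data (no randomness anywhere in fitting).
* AIC ties and duplicate candidates resolve to the smaller $G$; a failing
  candidate is recorded and skipped, and selection proceeds.
* A cluster with one subject is allowed; a design with a single cluster
  is rejected. Singular designs are rejected naming the collinear
  columns. Rows with missing SDEE cells are rejected at read time with a
  per-row message (the analytic contract requires complete curves).
* `run_full_analysis()` derives every seed from the master seed, stages
  its output files in a temporary directory, and moves them into place at
  the end; the same configuration yields byte-identical reports.

## Limitations

Three clusters identify a school variance only weakly; single-study ICC
estimates are noisy, and the Wald-z p-values are asymptotic. Quantile
fits at $\tau = 0.99$ with a few hundred subjects are flagged, not
suppressed. The bootstrap band is pointwise, not simultaneous, so reading
a significant window off the band carries the usual multiplicity caveat.
Quantile-crossing correction and joint multi-$\tau$ estimation are out of
scope (each $\tau$ is fitted separately).
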