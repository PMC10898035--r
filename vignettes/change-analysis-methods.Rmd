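---
title: "Change analyses for intermediate disease markers: models, estimands and bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change analyses for intermediate disease markers: models, estimands and bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(changepanel)
```

## The problem

Prospective cohort studies of diet (or other lifestyle exposures) and
continuous intermediate disease markers — weight, blood pressure, lipid
profiles, glycemia — use several superficially similar regression recipes:

* **concurrent change-change analysis** regresses the change in the marker on
  the change in exposure over the same interval,
  $\Delta y = \alpha + \beta\,\Delta x + \gamma\,\Delta z$;
* **change-score analysis** regresses the marker change on *baseline*
  exposure, $\Delta y = \alpha^* + \beta^* x_0 + \gamma^* z_0$;
* **lagged change-change analysis** regresses a *later* marker change on the
  *previous* interval's exposure change,
  $y_2 - y_1 = \alpha^{**} + \beta^{**}(x_1 - x_0) + \gamma^{**}(z_1 - z_0)$;
* plain **cross-sectional analysis** of one wave,
  $y_0 = \alpha^{***} + \beta^{***} x_0 + \gamma^{***} z_0$.

These are not interchangeable: they imply different causal models and target
different estimands. The concurrent model is the two-wave first-difference
form of the fixed-effects panel model

$$y_{it} = \beta x_{it} + \gamma z_{it} + u_i + \lambda_t + \epsilon_{it},$$

whose estimand is the *contemporaneous* effect $\beta$ of exposure on the
marker, and whose differencing removes any time-invariant individual term
$u_i$ (genetics, stable habits) — observed or not. Its validity rests on two
identification assumptions: *strict exogeneity* (the error at each wave is
mean-independent of regressors at every wave, ruling out lag effects,
outcome autocorrelation and reverse causation) and a *common trend*
(homogeneous time effects across individuals given measured confounders).
This package provides every ingredient needed to study, numerically and
analytically, what each of the four estimators converges to when those
assumptions hold and when they fail.

## The synthetic world

The generators implement three fully specified linear data-generating
processes over balanced panels of `n` individuals. All primitive draws
($z_{it}, u_i, \nu_{it}, \epsilon_{it}$, and $\lambda_{it}$ where present)
are independent standard normal by default, and the structural defaults are
$\beta = 1$, $\gamma = 1$, $\delta = 0.5$ (effect of $z$ on $x$), common
time effects $\lambda_t = (0.5, 1, 1.5)$, `n = 1000` — the stated conditions
of the simulation design this package reproduces, not tuning knobs. The
`sd_*` fields exist to support property tests and extensions only.

* **Baseline** (3 waves): $x_{it} = \delta z_{it} + \theta u_i + \nu_{it}$,
  $y_{it} = \beta x_{it} + \gamma z_{it} + u_i + \lambda_t + \epsilon_{it}$.
  $\theta \in [0, 1]$ scales unobserved time-invariant confounding.
* **Strict-exogeneity violation** (2 waves): the outcome gains a lag term
  $\rho\, y_{i,t-1}$, with pre-sample outcome
  $y_{i,-1} = u_i + \epsilon_{i,-1}$.
* **Common-trend violation** (2 waves): an individual time-varying
  confounder $\lambda_{it} \sim N(0,1)$ enters the exposure with loading 1
  and the outcome with loading $\omega \in [-1, 1]$. Following its
  structural equations literally, this process carries *no* common
  $\lambda_t$ term — the individual term replaces it.

What the generators deliberately do **not** emulate: unbalanced panels,
missing data, non-normal errors, measurement error in the exposure, more
than three waves, or effect sizes calibrated to any empirical cohort. A
green test therefore establishes internal consistency of estimator, theory
and simulation under this stated linear-normal world — not performance on
real cohort data.

Latent variables ($u_i$, $\lambda_{it}$, $y_{i,-1}$) are retained for
diagnostics in a quarantined attribute (`panel_latent()`); the observable
frame holds only `id, wave, x, y, z`, and the estimators refuse plain
tables that carry latent column names, so oracle information can never leak
into a fit.

## Estimators and their probability limits

All four analysis models are ordinary least squares with an intercept and
classical standard errors (one row per individual per model, so robust or
clustered variances would change nothing structural; the simulations vary
only coefficients). Covariance algebra on the structural equations gives
each estimator's probability limit, exposed by
`expected_probability_limit()`:

| estimator / process | probability limit | at unit variances, $\beta=1$ |
|---|---|---|
| concurrent, baseline | $\beta$ | $1$ for every $\theta$ |
| cross-sectional, baseline | $\beta + \dfrac{\theta \sigma_u^2}{\theta^2 \sigma_u^2 + \sigma_\nu^2}$ | $1 \to 1.5$ as $\theta: 0 \to 1$ |
| change-score, baseline | $-\dfrac{\beta \sigma_\nu^2}{\theta^2 \sigma_u^2 + \sigma_\nu^2}$ | $-1 \to -0.5$ |
| lagged, baseline | $-\beta/2$ | $-0.5$, free of $\theta$ |
| concurrent, SE violation | $\beta(1 - \rho/2)$ | $1 \to 0.5$ as $\rho: 0 \to 1$ |
| concurrent, CT violation | $\beta + \dfrac{\omega \sigma_\lambda^2}{\sigma_\lambda^2 + \sigma_\nu^2}$ | $0.5 \to 1.5$ as $\omega: -1 \to 1$ |

Sketch of the derivations (unit variances): partial the covariate term out
of the exposure regressor, then read off
$\mathrm{plim}\,\hat\beta = \mathrm{Cov}(y^\dagger, x^\dagger) /
\mathrm{Var}(x^\dagger)$ for the residualized pair. For the change-score
model the residualized baseline exposure is $\theta u + \nu_0$ and the
outcome change contains $-\beta \nu_0$, giving $-\beta/(\theta^2+1)$; for
the lagged model the residualized lagged exposure change is
$\nu_1 - \nu_0$, overlapping $\beta(\nu_2 - \nu_1)$ only in $-\beta\nu_1$,
giving $-\beta/2$; for the SE violation the lag feeds
$\rho(y_0 - y_{-1})$, whose only overlap with $\Delta\nu$ is
$-\rho\beta\nu_0$, giving $\beta(1-\rho/2)$; for the CT violation the
differenced individual trend $\Delta\lambda$ sits in both regressor and
outcome, giving $\beta + \omega/2$. None of these formulas is trusted until
it matches a single $n = 10^6$ simulated fit within $0.01$ — the test suite
performs that gate before any grid relies on the limits.

```{r plims}
expected_probability_limit("cross_sectional", "baseline", dgp_params(theta = 1))
expected_probability_limit("concurrent_cc", "ct_violation",
                           dgp_params(omega = -1, waves = 2))
```

## The Monte Carlo engine

`run_cell()` draws `replicates` panels, fits one estimator to each, and
reports the mean slope, the empirical SD of slopes and the mean model-based
SE. Both dispersion summaries are reported because "standard errors of the
estimates" is ambiguous between them; neither is an acceptance quantity.
`run_grid()` sweeps a structural parameter, and `run_config()` packages the
three canonical experiments (`theta_grid`, `rho_grid`, `omega_grid`, plus
the analytic `sem_checks`) into CSV-plus-manifest outputs.

Seeding is counter-based: replicate $r$ of a cell with base seed $b$ uses
`(b * 48271 + r) mod (2^31 - 1)`, and grid cell $j$ derives its base seed
from the experiment seed with counter $j \times 10^5$. Consequences worth
stating: results are bit-identical across re-runs and independent of
execution order, any single cell can be reproduced in isolation, and the
scheme is collision-free within a grid for any replicate budget below
48,271.

```{r mc, eval = FALSE}
spec <- grid_spec("baseline", "theta", seq(0, 1, 0.1),
                  c("concurrent_cc", "cross_sectional"),
                  replicates = 1000, base_seed = 1)
run_grid(spec, oracle = TRUE)
```

## The DAG engine

`build_fig1_sem()` encodes the three-wave panel DAG: per wave,
$Z_t \to X_t$ ($\delta$), $Z_t \to Y_t$ ($\gamma$), $X_t \to Y_t$
($\beta$), $U \to X_t$ ($\theta$), $U \to Y_t$ (1); no cross-wave edges, so
all serial dependence flows through $U$. The figure itself prints no
numbers on its arrows; binding them to the simulation parameters makes the
theoretical and Monte Carlo halves of the package one consistent object —
the SEM's implied law *is* the baseline process.

On top of the SEM: `implied_moments()` (exact covariance and means via
$(I-B)^{-1}$), `total_effect()` (path tracing), and
`regression_from_covariance()` (population least squares at infinite data).
Outcome changes such as $\Delta Y_1 = Y_1 - Y_0$ are handled as linear
contrasts of SEM variables (`sem_contrast()`), never as graph nodes; path
queries against a contrast run against each component with its $\pm 1$
weight. These reproduce, in closed form: the concurrent model recovers
$\beta$, $\gamma$ and intercept $\lambda_1 - \lambda_0$ exactly; the
change-score slope is $-\beta/(\theta^2+1)$ — neither the estimand nor its
negative once $\theta > 0$; the lagged slope is $-\beta/2$; the total
effects are $X_0 \to \Delta Y_1 = -\beta$, $X_0 \to \Delta Y_2 = 0$,
$X_1 \to \Delta Y_2 = -\beta$.

`enumerate_noncausal_paths()` lists every simple backdoor path between the
exposure and an outcome contrast and labels it open or blocked under a
conditioning set by the d-separation rules (non-colliders block when
conditioned on; colliders block unless they, or a descendant, are
conditioned on). The enumerator intentionally returns *all* simple backdoor
paths with status labels rather than asserting that a fixed number exist:
the five textbook paths for $X_0 \to \Delta Y_1$ under conditioning
$\{Z_0, X_1, Z_1\}$ form a subset (paths that are blocked at an
unconditioned collider such as $Y_0$ are usually left off of hand-drawn
lists), and the test suite pins the full count against an independent
exhaustive search.

```{r dag}
sem <- build_fig1_sem(dgp_params(theta = 1))
enumerate_noncausal_paths(sem, "X0", sem_contrast("dY1", "Y1", "Y0"),
                          conditioning = c("Z0", "X1", "Z1"))
```

One analytic subtlety uncovered while verifying the path-cancellation
claim: the offsetting of the two backdoor paths through $U$ into $Y_0$ and
into $Y_1$ (which requires equal outcome loadings of $U$ at both waves) is
visible in the *unconstrained* form of the concurrent model
($\Delta Y \sim X_0 + X_1 + Z_0 + Z_1$), where the $X_0$ coefficient equals
$-\beta$ exactly when the loadings agree and departs otherwise. The
*differenced* slope is insensitive to unequal outcome loadings as long as
the $U \to X$ loadings agree across waves, because $u$ then cancels out of
the exposure change entirely.

## Numerical choices and degenerate inputs

* OLS is solved by pivoted QR; rank deficiency raises an error naming the
  collinear terms, and designs with fewer rows than columns are refused.
* Differences are always later-minus-earlier; waves are 0-indexed.
* The implied covariance is symmetrized after assembly and checked positive
  semi-definite to $-10^{-10}$ in the tests.
* Monte Carlo summary CSVs round to three decimals, matching the precision
  at which such results are conventionally reported; returned data frames
  keep full precision.
* Grid values, not parameter names, order the output; within a value,
  estimators keep their requested order.

## Design choices where the design was open

* The SE-violation process keeps the common time effects
  $\lambda_0 = 0.5, \lambda_1 = 1$ of the baseline; the CT-violation
  process omits the common term because its structural equations do.
* All four analysis models carry an intercept; its interpretation is only
  meaningful for the differenced models (it estimates
  $\lambda_{\text{later}} - \lambda_{\text{earlier}}$), but symmetry keeps
  the fitted objects uniform.
* Cross-sectional analysis defaults to wave 0, the wave written in its
  model.
* Coefficients are uniformly named `intercept`, `x`, `z` across models;
  `model_id` records which design they belong to.
* There is no shell executable: `run_config()` plus `write_panel()` /
  `read_panel()` and the fit functions are the scripting surface.

## Limitations

Everything here is linear-Gaussian with exact model knowledge; the bias
magnitudes are properties of this stated world, not forecasts for any real
cohort. Estimation under violated assumptions is diagnosed, not repaired —
dynamic panel estimators (lagged dependent variable with instruments) and
individual-slope fixed-effects models, the standard repairs, are out of
scope, as are unbalanced panels and robust variance estimation.
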