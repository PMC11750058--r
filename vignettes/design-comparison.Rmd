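---
title: "Panel designs for unobserved confounding: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel designs for unobserved confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcausal)
```

## The inference problem

Observational site-by-year surveys confound spatial gradients: a site
that is warm is usually warm *for a reason*, and that reason often
shapes the outcome through other channels. In the package's running
system, snail abundance $S_{ij}$ at site $i$ in year $j$ follows

$$S_{ij} = \beta_0 + \beta_1 x_{ij} + \gamma w_i + \varepsilon_{ij},$$

with yearly temperature $x_{ij}$ observed and site recruitment $w_i$
unobserved. A latent oceanographic driver $O_i$ raises site mean
temperature ($T_i = 2 O_i + 15$) while lowering recruitment
($R_i = -2 O_i + 10$), so $\mathrm{Cov}(x, w) \ne 0$ and the pooled
slope converges to $\beta_1 + \gamma\,\mathrm{Cov}(x, w)/\mathrm{Var}(x)$
rather than $\beta_1$. With the default parameters that limit is
$1 - 4/5 = 0.2$: a severe, purely structural bias that no sample size
cures.

Every design in the menu is a different answer to the same question:
which part of the variation in $x$ is clean of $w_i$? Site-level
confounders are constant within a site, so *within-site* variation is
clean; the designs differ in how they isolate it.

## The design menu and its algebra

**Within transformation** (`fe_within`) subtracts site means from
outcome and exposure and regresses
$y_{ij} - \bar y_i$ on $x_{ij} - \bar x_i$ with no intercept. Anything
constant within a site — including $\gamma w_i$ — is annihilated
algebraically. **Dummy coding** (`fe_dummy`) fits the same model with
one mean-coded intercept $\lambda_i$ per site and no global intercept;
the slope and its standard error are identical (the within fit reports
residual degrees of freedom $n - n_{\mathrm{sites}} - 1$ so the two
parameterisations agree exactly).

**Group mean covariate** (`group_mean_covariate`) regresses $y$ on
$x_{ij}$ *and* the site mean $\bar x_i$ (the Mundlak device). The
$\bar x_i$ coefficient $\beta_2$ soaks up the between-site gradient
(causal plus confounded); the $x_{ij}$ coefficient is then the within
effect. **Group mean centering** (`group_mean_centered`) is the
reparameterisation that regresses on the anomaly $x_{ij} - \bar x_i$
and on $\bar x_i$; its between coefficient satisfies
$\beta_2^{cent} = \beta_1 + \beta_2^{mund}$ exactly, and both designs
return the same $\beta_1$ as the fixed-effects fits on balanced
panels (an identity the test suite asserts at $10^{-6}$ per
replicate). Both can be estimated by OLS or with a site random
intercept via REML; on balanced panels the point estimate of
$\beta_1$ is unchanged, while the random effect changes the standard
errors and the handling of unbalanced data.

**Random intercept** (`random_effects`) models the site deviation as
part of the error, $\delta_i \sim N(0, \sigma^2_{site})$. Its GLS
slope is a precision-weighted compromise between the within estimator
and the between (site-means) estimator, and therefore lies between
them on every panel — another property the suite checks numerically.
When the random-effects assumption fails (here, by construction,
$\delta_i$ contains $\gamma w_i$ which is correlated with $x$), the
between component drags the estimate toward the confounded gradient.

**Differencing** (`first_difference`, `second_difference`) targets
confounders that *trend* within sites. First differences
$\Delta y_{ij} = \beta_1 \Delta x_{ij} + \lambda_i + \Delta\varepsilon_{ij}$
turn a site-specific linear trend into a site constant $\lambda_i$,
estimated as a per-site intercept; second differences remove
$\lambda_i$ without estimating it. Differences are formed only across
consecutive years (time step of exactly 1); gaps produce no row and
are logged, so gapped panels lose information rather than silently
mixing horizons.

**Two-way designs** (`twoway_fe`, `twoway_mundlak`) address
confounders that vary by site *and* year (e.g. cold-water pulses that
bring recruitment). With multiple plots per site, plot intercepts
$\lambda_k$ and site-by-year intercepts $\eta_{ij}$ absorb both
layers; the Mundlak analogue replaces the intercepts with plot means
and site-year means plus two random intercepts. With one plot per
site the site-year terms saturate the data and the fit refuses, by
design. The fixed- and random-effects versions agree only in the
large-variance-ratio limit, so the tests compare them within the
estimate's standard error rather than to machine precision.

## The synthetic-data generator

`dgp_config()` defaults encode the study conditions: 10 sites, 10
years, $O_i \sim N(0,1)$, $R_i = -2O_i + 10$, $T_i = 2O_i + 15$,
$T_{ij} \sim N(T_i, 1)$, $S_{ij} \sim N(T_{ij} + R_i, 1)$, true
temperature effect 1. The location shifts (10, 15) are additive
constants, not empirical renormalisations, so
$\mathrm{corr}(T_i, R_i) = -1$ holds exactly in every truth record.
Gaussian outcomes may go negative; no truncation is applied, keeping
every estimator's linear algebra exact.

Variants alter one mechanism at a time. `no_confounding` sets the
recruitment slope to zero, making temperature exogenous — the control
condition under which even the naive estimator is unbiased.
`site_trend` draws site trend slopes $\lambda_i \sim N(0, 0.5^2)$ and
adds $\lambda_i t$ to both a development-like confounder in the
outcome and (by default) the exposure; 0.5 makes the trend signal
comparable to the yearly temperature noise, large enough to visibly
bias the naive fit while leaving the differencing designs their
within-site variation. `spatiotemporal` gives each site 4 plots and
site-year pulses $P_{ij} \sim N(0,1)$ entering temperature with slope
−2 and recruitment with slope +2 (cold pulses, high recruitment),
plus plot intercepts with SD 1; these mirror the magnitude of the
site-level confounding one level down. Only the snail variant's
parameters are canonical; the trend and pulse magnitudes are this
package's own documented defaults, chosen once for realism.

Randomness uses L'Ecuyer–CMRG streams: replicate $r$ owns stream $r$
of the master seed and each generation stage (oceanography, trends or
pulses, yearly temperature noise, outcome noise, plot effects) its
own substream. Adding a stage or drawing more numbers in one stage
never perturbs other stages or replicates, and any replicate can be
regenerated alone.

What the generator does *not* emulate: count-valued or otherwise
non-Gaussian outcomes, serial correlation beyond site constants and
linear trends, spatial autocorrelation between sites, measurement
error in temperature, and missingness. Passing tests therefore show
the estimators' algebra and sampling behaviour under clean Gaussian
conditions, not robustness to the full mess of field data.

## Monte-Carlo engine and interval conventions

`run_study()` fits every design in the menu to each replicate panel
and aggregates the exposure-effect estimates: mean, sample standard
deviation (denominator $n-1$, i.e. the spread of point estimates
across replicates), the fraction of interval estimates containing
zero, and the fraction excluding the true effect. Intervals default
to estimate ± 2 SE — the convention the comparison table is defined
by — with a $t$-quantile rule available; boundary values count as
contained. Replicates on which a design fails (e.g. second
differences on a two-year panel) are excluded from that design's
aggregates and counted in `n_converged`, rather than discarding the
replicate for every design. The shipped nine-design menu
(`table1_designs()`) pairs each group-mean design with and without a
site random effect; the second-difference design is available but not
part of the shipped menu.

## Numerical choices

* **Least squares** uses pivoted QR with a relative rank tolerance of
  $10^{-10}$; collinear columns are dropped and reported by name (the
  two-way fixed-effects design relies on this to resolve the inherent
  plot/site-year overlap). Model standard errors use
  $\hat\sigma^2 (X'X)^{-1}$; CR1 cluster-robust errors apply the
  $G/(G-1)\cdot(n-1)/(n-k)$ small-sample factor and are cross-checked
  against an independent sandwich implementation in the tests. With a
  single cluster the factor is undefined and the fit falls back to
  model-based errors with a warning.
* **REML** is profiled: for a variance ratio
  $\theta = \sigma^2_{site}/\sigma^2$, fixed effects are GLS and
  $\sigma^2$ has a closed form, leaving a one-dimensional criterion
  minimised on $\log\theta$ over $[10^{-8}, 10^8]$ (tolerance
  $10^{-10}$), with both boundary values checked so a zero-variance
  solution lands cleanly on the boundary. The single-component solver
  uses closed-form per-group algebra; the two-component solver uses
  the Woodbury identity on the combined random-effect design matrix
  and nests two one-dimensional searches. Both match the reference
  mixed-model implementation (`lme4`) to well under $10^{-4}$
  relative error in the tests. REML (not ML) is used throughout,
  matching the default of the mixed-model tools ecologists use.
* **Degenerate inputs** raise classed estimation errors rather than
  returning nonsense: no within-site exposure variance (within and
  group-mean designs), constant exposure after double differencing,
  saturated site-year effects, rank-zero systems.
* **Missing data** are dropped (and counted) at read time, so every
  estimator sees complete cases; unbalanced groups use their own
  observed $n$ in means, and the algebraic-equivalence claims are
  asserted only for balanced panels.

## Problem sizes used by the checks

The shipped comparison runs 100 replicates of the 10 × 10 system
(seconds, including 300 REML fits). Unbiasedness checks use 1000
replicates for the cheap estimators; the analytic pooled-slope limit
is checked on five 200 × 200 panels averaged (a single panel of that
size still carries ~0.016 sampling noise in the slope through the
200 site draws); generator moment checks use 10,000 sites. All checks
compare Monte-Carlo quantities within three Monte-Carlo standard
errors computed from the run itself.

## Known limitations

Linear, additive, homogeneous effects only — no GLM links, random
slopes, interactions of the causal effect with confounders, staggered
or heterogeneous treatment timing, instrumental variables or
sensitivity analysis. Inference options are model-based and CR1
standard errors with ±2 SE or $t$ intervals; no bootstrap. The
two-way designs assume permanent plots; re-randomised plots would
need the plot terms dropped, which the design menu does not automate.
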