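# panelcausal

Estimating causal effects from observational ecological data is haunted
by omitted variable bias: an unmeasured driver that shapes both the
exposure and the outcome pushes the regression slope away from the
causal effect, no matter how much data is collected. `panelcausal` is
an R toolkit for the family of clustered/panel designs that remove this
bias by exploiting repeated observation of the same sites over time —
plus a confounded-panel simulator and a Monte-Carlo study engine for
comparing the designs head to head. It is aimed at ecologists and
biostatisticians analysing site-by-year (or plot-in-site-by-year)
survey data.

## The model

The running system is a snail survey: abundance `S_ij` at site `i` in
year `j` responds to yearly temperature `x_ij` (effect `β1`, the target
of inference) and to site recruitment `w_i`, which is unmeasured.
Because a latent oceanographic driver raises site temperature while
lowering recruitment, temperature is endogenous across sites, and the
pooled ("naive") regression

    S_ij = β0 + β1 x_ij + ε_ij

converges to `β1 + γ·Cov(x, w)/Var(x)` instead of `β1`. The design
menu:

| design | idea |
|---|---|
| `naive` | pooled OLS, no site terms |
| `random_effects` | Gaussian site intercept, REML; assumes the intercepts are uncorrelated with `x` (violated here, hence biased) |
| `fe_within` | subtract site means from `y` and `x` (within transformation) |
| `fe_dummy` | one mean-coded intercept per site; identical slope to `fe_within` |
| `group_mean_covariate` | Mundlak device: add the site-mean exposure as a covariate (with/without a site random effect) |
| `group_mean_centered` | within/between decomposition: site-centred anomaly plus site mean |
| `first_difference` | consecutive-year differences with per-site intercepts (site trend slopes) |
| `second_difference` | difference the differences; removes site-specific linear trends without estimating them |
| `twoway_fe` | plot intercepts plus site-by-year intercepts (spatiotemporal confounding) |
| `twoway_mundlak` | plot means and site-year means with plot and site-year random intercepts (two-component REML) |

All random-intercept fits use a REML criterion profiled over the
variance ratio(s) with GLS fixed effects; cluster-robust (CR1)
standard errors are available for the OLS-based designs.

## Worked example

```r
library(panelcausal)

sim <- simulate_panel(dgp_config(seed = 1))   # 10 sites x 10 years
fit_naive(sim$panel)
fit_fe_within(sim$panel)
```

```
<fit_result> design: naive  (n = 100, units = 10, dof = 98, SE: model)
        term estimate       se    ci_low  ci_high
 (Intercept) 23.13700 0.884960 21.367000 24.90700
           x  0.13277 0.057296  0.018178  0.24736
residual sigma2 = 1.715
<fit_result> design: fe_within  (n = 100, units = 10, dof = 89, SE: model)
 term estimate       se  ci_low ci_high
    x  0.87943 0.097922 0.68358  1.0753
residual sigma2 = 0.95753
```

The true temperature effect in this simulation is 1. The naive slope
(0.13) is destroyed by the cross-site confounding; the within
estimator (0.88 ± 0.10) brackets the truth because subtracting site
means removes everything that is constant within a site — including
the unmeasured recruitment.

The Monte-Carlo comparison over 100 replicate panels:

```r
res <- run_study(study_config(dgp = dgp_config(seed = 1), n_reps = 100))
res
```

```
                   design mean_estimate sd_estimate frac_ci_contains_zero frac_ci_excludes_truth
                    naive        0.2430     0.11440                  0.09                   1.00
           random_effects        0.8703     0.13520                  0.00                   0.20
                fe_within        0.9939     0.08199                  0.00                   0.02
                 fe_dummy        0.9939     0.08199                  0.00                   0.02
  group_mean_covariate_re        0.9939     0.08199                  0.00                   0.02
   group_mean_centered_re        0.9939     0.08199                  0.00                   0.02
 group_mean_covariate_ols        0.9939     0.08199                  0.00                   0.01
  group_mean_centered_ols        0.9939     0.08199                  0.00                   0.01
         first_difference        0.9949     0.11160                  0.00                   0.06
```

The naive mean lands on its analytic limit (0.2 = 1 − 4/5), the
random-effects model splits the difference between the biased between
gradient and the clean within signal, and the four fixed-effects /
correlated-random-effects designs give identical slopes replicate by
replicate. `export_table()` writes the summary and the per-replicate
estimates as tidy CSVs.

## Command line

A thin wrapper over the same functions is installed as `exec/panelcausal`:

```sh
panelcausal simulate --seed 1 --out panel.csv
panelcausal fit --design fe_within --data panel.csv
panelcausal study --config inst/extdata/study_table1.json --out results/
```

Every run writes a `*.manifest.json` recording the resolved
configuration and seed, sufficient to reproduce the outputs exactly.
Exit codes: 0 success, 1 configuration/validation error, 2 estimation
error.

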