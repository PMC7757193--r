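# metaspom

Stochastic patch occupancy models (SPOMs) for **interacting
metapopulations**: analyse and simulate the joint colonization–extinction
dynamics of a small set of species — here a butterfly host (M), its
specialist parasitoid (C, which cannot occur without the host), and a
host-plant mildew (P) — sharing a network of habitat patches surveyed yearly
for presence/absence. The package is aimed at landscape and disease
ecologists working with long-term multi-species patch-occupancy surveys, and
at anyone who wants a fully synthetic, ground-truthed test bed for
metacommunity occupancy methods.

## The model

Per-patch connectivity for species *Y* uses a negative-exponential dispersal
kernel over occupied neighbours,

```
S_it^Y = Σ_{j≠i} exp(−α d_ij) · A_j · O_{j,t−1}^Y ,
```

with `d_ij` the inter-patch distance (km), `A_j` the patch area (m²) and
`1/α` the mean dispersal distance (default 1 km). Colonization and
extinction probabilities are modelled on the logit scale with crossed patch
and year random intercepts,

```
logit c_it (or e_it) = β0 + Σ_j βj x_ijt + γ_year(t) + γ_patch(i),
```

fitted by Laplace-approximated ML (`lme4`). Covariates: log host-plant
cover, an ordinal second-host score, connectivity, a road-border flag, and
AIC-selected log monthly precipitation terms (all 2⁴ = 16 month subsets are
ranked). Species interactions are screened by adding the previous-year
community **patch state** (one of `0, M, MC, MCP, MP, P`) as a fixed factor
and comparing AICs. One-step forecasts combine the rates as
`p = o(1−e) + (1−o)c`, with 95% prediction intervals from 1,000 parametric
bootstrap draws plus Bernoulli observation noise, and community assembly
enforces the host constraint in every draw. A closed-loop simulator
propagates whole metacommunities for decades, recomputing connectivity from
the simulated occupancy each year (100-replicate ensembles by default).

## Worked example

Generate a ground-truthed synthetic landscape (500 patches × 19 years),
count turnover events, and fit the butterfly colonization model:

```r
library(metaspom)
fx <- make_fixture("default", seed = 1, dir = tempdir())

assign_turnover_events(fx$history, "M")
#> <turnover_events> species M
#>   colonizations: 435 / 7780 possible (5.6%)
#>   extinctions:   463 / 1220 possible (38.0%)

tab <- build_transition_table(fx$history, fx$patches, fx$precip,
                              species = "M", response = "colonization")
fit <- fit_occupancy_glmm(tab, c(covariate_terms("M"), "logp_may"))
fit
#> <spom_fit> colonization [M]
#>             estimate    se
#> (Intercept)   -6.806 1.489
#> log_cover      0.671 0.066
#> vs             0.476 0.061
#> conn           0.019 0.001
#> road           0.404 0.146
#> logp_may       0.279 0.368
#> sigma2_patch = 0.536, sigma2_year = 0.343
#> logLik = -1234.42, AIC = 2484.84, n = 7780
```

The slopes are log-odds per covariate unit: each unit of log host-plant
cover raises the colonization odds by `exp(0.671) ≈ 2`, and the recovered
values sit near the generating truth (0.7, 0.5, 0.018, 0.35, 0.2).
`r2_nakagawa(fit)` reports marginal/conditional r² of 0.30/0.45 — fixed
effects explain 30% of the link-scale variance, patch and year effects
another 15%. The interaction screen on the same rows,

```r
scr <- state_effect_screen(tab, fit$terms)
scr$delta_aic   #  1.4  -> no support for a patch-state effect (none simulated)
scr$rates
#>   state rate_pct     lo95     hi95
#> 1     0 2.171500 1.583085 2.972019
#> 2     P 2.507666 1.597634 3.915437
```

shows colonization rates of ~2.2% into empty patches vs ~2.5% into
mildew-occupied ones, with ΔAIC = +1.4: correctly no evidence for an
interaction, since this fixture was generated without one. From here,
`bootstrap_predictions()` + `summarize_forecast()` give per-year and
per-cover-class prediction intervals, `simulate_ensemble()` runs the
closed-loop metacommunity simulation, and `run_pipeline(pipeline_config(...))`
executes the whole chain (events → fits → screens → forecast → simulation)
into a directory of CSV/JSON artifacts.

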