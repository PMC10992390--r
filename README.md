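# bruvshealth

Hierarchical Bayesian health assessment and monitoring-design power
analysis for baited-video fish counts.

## What it is for

Community-based marine monitoring programs track culturally and
economically important fish with baited remote underwater video stations
(BRUVS) and report status against a traffic-light system — *poor*,
*fair*, *good*, *very good* — relative to a baseline year. This package
turns deployment-level counts (summed MaxN over the indicator taxa) into
that report, with uncertainty attached, and quantifies how likely the
monitoring design is to detect a future decline. It is written for
quantitative ecologists supporting such programs.

## The model

Counts follow a negative binomial with crossed random deviations on the
log scale:

```
A ~ NB(mu, phi),   Var(A) = mu + mu^2 / phi
ln(mu) = beta0 + Delta_B + Delta_S + Delta_Y + Delta_S:Y
Delta_* = zeta_* sigma_*,   zeta_* ~ N(0, 1)
beta0 ~ N(0, 1);  sigma_* ~ Gamma(2, 2);  phi ~ Gamma(2, 1)
```

with station (`B`), site (`S`), year (`Y`) and site-by-year (`S:Y`)
deviations. Posterior sampling is by MCMC (JAGS). Year-to-baseline fold
change is `exp(Delta_Y=y - Delta_Y=base)` per draw (site-specific
variants add the interaction terms), and each health category's
credibility is the share of fold-change draws in its band:
`[0, 0.5)` poor, `[0.5, 0.7)` fair, `[0.7, 0.9)` good, `[0.9, Inf)`
very good by default (a fold change of 0.68 is *fair*; 1.06 is
*very good*).

The design evaluation simulates background years plus a disturbed new
year whose mean is the baseline level times a decline multiplier `rho`,
refits the model with a before/after dummy `X`
(`ln(nu) = ln(mu) + beta1 * X`), and reports the mean
`P(beta1 < 0 | data)` over replicates — the power to detect that
decline — across a `rho` x sampling-effort grid (the default grid is
6 x 3 cells x 500 replicates = 9,000 model runs).

## Worked example

Simulate a realistic five-site monitoring dataset (108 deployments,
mean combined MaxN 13.5, over-dispersion phi = 1.82), fit the model,
and assess 2020 against the 2018 baseline:

```r
library(bruvshealth)

sim <- simulate_counts(study_design(), default_generative_parameters(),
                       seed = 11)
fit <- fit_abundance_model(sim$table,
                           model_config(n_chains = 4, draws = 10000,
                                        seed = 11))
classify_health(fold_change_draws(fit, year = 2020))
```

```
health_assessment (2020 vs 2018): modal category very_good
  poor         0.0%
  fair         0.1%
  good         0.6%
  very_good   99.3% 
  P(decline) = 1.7%  [10000 draws]
```

Read: given this (synthetic) dataset, 2020 abundance is almost
certainly within 10% of baseline or above it (99% credibility on
*very good*), and the chance that it declined at all is under 2%.
`assess_health(fit, by_site = TRUE)` produces the same table per site,
and `diagnostics_report(fit)` prints split R-hat, 95% highest-density
intervals and the Bayesian R-squared.

A small power check — how often would a 30% decline be flagged at 20
deployments per site?

```r
res <- run_power_grid(power_grid(rho = 0.7, alpha = 20, n_replicates = 10),
                      default_generative_parameters(), root_seed = 1)
summarize_power(res)[, c("rho", "alpha", "power", "mc_se")]
```

```
  rho alpha    power      mc_se
1 0.7    20 0.584375 0.07729986
```

So with ten quick replicates the mean probability of calling the
decline is about 0.58 — detection of a 30% drop in a single year is
far from assured, which is exactly what the design evaluation is meant
to reveal. The `cli_simulate()` / `cli_fit_assess()` / `cli_power()`
functions run the same stages from YAML configs and write CSV outputs
plus a run manifest (see also the thin wrapper in `inst/cli/`).

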