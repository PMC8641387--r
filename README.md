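# devwild

Tools for a cross-national analysis linking change in country-level
Sustainable Development Goal (SDG) indicators to wildlife population
abundance trends. The package is aimed at macroecologists and conservation
scientists who work with Living-Planet-style abundance time series on one
side and World-Bank-style country-by-indicator panels on the other, and who
want the full chain — trend derivation, panel pruning, indicator
preprocessing, hierarchical regression — as tested, reusable functions
rather than a one-off script.

## What it computes

Every yearly series (a population's abundance, or one country's values for
one indicator) is reduced to a **mean annual change**: series with fewer
than 6 observations get an OLS fit with linear-interpolated gap years;
longer series get a penalized cubic regression spline (`mgcv`) with basis
dimension `ceil(n/2)`; annual changes are consecutive differences of the
(predicted) yearly values, clipped to the study window (1996-2015 by
default), and retained only when R² > 0.5 and the clipped changes span at
least 5 years. Abundance is log10-transformed first, so trends are in log10
units/yr.

The sparse country × indicator panel of retained trends is **homogenized**
in three fixed steps (drop countries below half the indicator set; drop
indicators with too few associated wildlife populations; drop countries
with incomplete remaining data), indicator trends are oriented so larger =
more desirable progress and z-scored across countries, and each wildlife
trend is cross-joined with its country's indicator trends.

For each indicator *k* and taxon class, a univariate Bayesian hierarchical
model is fitted by a conjugate Gibbs sampler:

    y_i = β₀ + β₁ x_i + β₂ log₁₀(area) + β₃ log₁₀(HPD₁₉₉₆)
          + u_species + u_order + u_region + ε_i

with βⱼ ~ N(0, 1000), u_g ~ N(0, σ²_g), precisions ~ Gamma(1, 5e-5). The
headline output per indicator is the posterior of β₁ — response-trend units
per 1 SD of oriented indicator trend — its 95% equal-tailed credible
interval, the proportional form 10^β₁ − 1, and a support flag (CI excludes
zero), with split-R̂ / ESS convergence checks.

A synthetic-data generator with stored ground truth (`simulate_panel()`)
exercises the whole chain end to end, so parameter recovery and
credible-interval calibration are testable without any external data.

## Worked example

```r
library(devwild)

cfg <- synth_config(n_countries = 20, n_populations_per_country = 8,
                    n_indicators = 3,
                    beta_true = c(ind01 = 0.8, ind02 = 0, ind03 = -0.4),
                    seed = 11)
run <- run_pipeline(cfg, min_populations = 5, chains = 2,
                    iter = 2000, burnin = 500)
run
#> devwild pipeline run
#>   trends retained for 157 populations, in 20 countries, with 3 indicators
#>   471 modelling rows; 6 fits (6 converged, 2 supported)
#>   recovery: coverage 1.00, sign accuracy 1.00

print(run$posteriors)
#> posterior summaries: 6 fits, 2 with 95% CI excluding zero
#>  taxon_class indicator_code  n beta_mean  ci_low ci_high support   rhat converged
#>         bird          ind01 79   0.66127  0.4900  0.8332    TRUE 1.0004      TRUE
#>         bird          ind02 79   0.15568 -0.2025  0.5192   FALSE 0.9999      TRUE
#>         bird          ind03 79  -0.10085 -0.4745  0.2669   FALSE 1.0001      TRUE
#>       mammal          ind01 78   0.64379  0.4694  0.8113    TRUE 0.9999      TRUE
#>       mammal          ind02 78   0.15581 -0.2066  0.5035   FALSE 0.9998      TRUE
#>       mammal          ind03 78  -0.09631 -0.4507  0.2520   FALSE 0.9995      TRUE
```

The planted effects were 0.8, 0 and −0.4 (log10 units/yr per 1 SD): the
credible intervals cover them for every fit (`run$recovery` reports
coverage 1.00 and sign accuracy 1.00 here), and only the strong effect
reaches support — the −0.4 effect is within its wide, honest interval of
zero at this country count. `run$forest` holds the
forest-plot table on the proportional-change scale, with inverted
indicators marked by an asterisk; `write_run(run, dir)` writes every stage
table plus a JSON manifest whose per-stage counts reconcile exactly with
the CSVs.

Real data enter through the same schema: pass
`data = list(abundance = ..., indicators = ..., indicator_meta = ...,
country_meta = ...)` to `run_pipeline()` (see `?simulate_panel` for the
column layouts) and use `min_populations = 160` for full-scale panels.

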