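---
title: "Methods: linking development-indicator change to wildlife abundance trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking development-indicator change to wildlife abundance trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

devwild implements a cross-national analysis that asks whether change in
country-level indicators of human development (SDG-style indicators: GDP per
capita, access to water, governance indices, human population density, and so
on) is associated with trends in wildlife population abundance. The analysis
has four stages, each exposed as package functions so every stage is testable
in isolation:

1. **Trend chain** (`fit_trend()`, `batch_trends()`, `wildlife_trends()`,
   `indicator_trends()`): every yearly series — a wildlife population's
   abundance or one country's values for one indicator — is reduced to a
   single *mean annual change* with quality filters.
2. **Homogenization** (`homogenize_panel()`): the sparse country-by-indicator
   panel of retained trends is pruned to a complete block.
3. **Orientation and normalization** (`zscore_orient()`,
   `assemble_model_rows()`): indicator trends are oriented so larger means
   "more desirable progress", z-scored across countries, and cross-joined
   with the wildlife trends of their country.
4. **Hierarchical regression** (`bhlm()`, `fit_indicator_models()`): one
   univariate Bayesian linear mixed model per indicator and taxon class,
   with species, taxonomic-order and region random intercepts, fitted with a
   conjugate Gibbs sampler written for exactly this model class.

A synthetic-data generator (`simulate_panel()`) with stored ground truth
makes the whole chain verifiable end to end (`run_pipeline()`,
`recovery_report()`).

# Trend chain

Abundance values are log10-transformed. Trends are therefore in log10 units
per year throughout; the reporting stage also carries the proportional form
$10^{\beta}-1$. Zeros are replaced by 1% of the series mean before logging
(`zero_replace_frac`), and an all-zero series is rejected: no log scale can
represent it.

Indicator series use two preprocessing flags. Indicators in monetary or
population-size units are log10-transformed (`log_required`). Indicators
that can be negative anywhere across countries (governance indices) are
shift-centered first: each country's series has the *cross-country* minimum
subtracted, plus a small `shift_eps` (default 0.01) so the minimum itself
remains representable under a subsequent log. Using the cross-country (not
per-series) minimum keeps the shift a constant within an indicator, so
trends — which are differences — are unaffected by it.

Series with fewer than 6 *observations* are fitted by ordinary least squares
of value on year; gap years are filled by linear interpolation (`zoo`).
Series with 6 or more observations are fitted by a penalized cubic
regression spline (`mgcv::gam`) with basis dimension $k = \lceil
n_{\mathrm{obs}}/2\rceil$ — the "smoothing parameter at half the series
length" convention from the Living-Planet trend literature — and predicted
at every integer year of the observed span. We count observations, not span
years, for the 6-observation switch: the input rules already impose a
5-year minimum span and a 2-observation minimum, and an observation count is
the only reading under which the thresholds are not redundant.

Annual changes are consecutive differences of the yearly (predicted) values.
The change labelled with year $t$ covers $t-1 \to t$, and is kept only when
both endpoints lie inside the study window (default 1996-2015). Fitting uses
all observed years and only the changes are clipped; the alternative
(clipping before fitting) discards information at the window edges for no
gain.

On the linear path the annual changes come, by default, from the
observed/interpolated values, with the regression serving as the fit-quality
gate (`linear_changes_from = "interpolated"`). The alternative reading —
differences of the fitted line, making every change equal to the slope — is
available as `linear_changes_from = "fitted"`. Both are defensible
readings of "change in (predicted) values" for a linear fit; the default
follows the interpolate-then-difference convention, and the switch makes the
choice auditable.

Retention requires (a) $R^2 > 0.5$, strictly, and (b) window-clipped annual
changes spanning at least 5 years (counting both endpoints of the covered
interval). $R^2$ is defined uniformly for both paths as the squared Pearson
correlation between fitted and observed values at the observed years; a
constant series, whose correlation is undefined, gets $R^2 = 0$ and a
distinct `constant_series` rejection label rather than an arbitrary pass.
The retained trend is the arithmetic mean of the clipped annual changes.

# Homogenization

Real country-by-indicator panels have strongly misaligned gaps. Three steps,
in a fixed order, produce a complete block:

1. drop countries holding fewer than `ceil(min_indicator_fraction * n)`
   indicators (default fraction 0.5 — with 42 indicators this is the
   "fewer than 21" cut);
2. drop indicators whose associated wildlife-population total over the
   *remaining* countries is below `min_populations` (default 160; the
   population counts are of retained populations, after the trend filters,
   because homogenization operates on the trend panel);
3. drop any remaining country missing one of the retained indicators.

The order is load-bearing (step 2 must not count populations of countries
already removed in step 1) and tested against brute-force enumeration.
Because a step-3 removal can push an indicator's population total back
below the step-2 threshold, a single pass over the steps is not a closure
operation; the steps are repeated, in the same order, until nothing
changes, so the result is a true fixed point and homogenization is
idempotent by construction (a `iterate = FALSE` switch gives the literal
single pass). An emptied panel is an explicit error naming the binding
step, never a silent empty result.

# Orientation, normalization, assembly

Some indicators run "downhill" (e.g. population living in slums): their
trends are multiplied by -1 so that for every indicator a larger oriented
trend means more desirable progress. Orientation happens *before*
z-scoring, so flipping a flag exactly negates the z-scores. Each indicator's
oriented trends are then centered and scaled across countries — sample SD
(n-1) by default, population SD by config; with three countries at trends
1, 2, 3 both conventions agree on z = (-1, 0, 1). A regression coefficient
downstream is therefore "response-trend units per 1 SD of oriented
indicator trend". Indicators with zero cross-country SD are excluded with a
logged reason.

Each retained wildlife trend is cross-joined with every retained indicator
z-score of its country, together with log10 country land area and log10
1996 human population density as fixed covariates. Birds and mammals are
carried as separate datasets and modelled separately.

# The hierarchical model and its sampler

For one indicator and one taxon class:

$$y_i = \beta_0 + \beta_1 x_i + \beta_2 \log_{10}(\mathrm{area}_i)
      + \beta_3 \log_{10}(\mathrm{HPD}_i)
      + u_{s(i)} + u_{o(i)} + u_{r(i)} + \varepsilon_i$$

with $y_i$ the population's wildlife trend, $x_i$ its country's z-scored
indicator trend, random intercepts for species, taxonomic order and region,
$u_g \sim N(0, \sigma_g^2)$, and $\varepsilon_i \sim N(0, \sigma^2)$. Every
fixed effect, the intercept included, carries the vague prior
$N(0, 1000)$; each precision ($1/\sigma^2$, $1/\sigma_g^2$) carries a
Gamma(1, 5e-5) prior, the standard vague default for this model family.
Both choices are config-exposed (`fixed_prior_var`, `prec_prior`).

The model is linear-Gaussian throughout, so all full conditionals are
conjugate and `bhlm()` samples the exact posterior by Gibbs:

* single-site normal updates for each fixed effect. Single-site updates
  (rather than one blocked multivariate-normal draw) are chosen because,
  combined with the sign convention below, they make the sampler *pathwise*
  equivariant to sign flips of any design column — flipping an indicator's
  orientation flag exactly negates that coefficient's draws and leaves all
  other draws bit-identical under the same seed, an auditable invariant of
  the reporting pipeline. Non-intercept columns are mean-centered
  internally (restoring most of the mixing a blocked update would give);
* blocked normal updates for each random-intercept vector, followed by
  *translation moves*: for every fixed effect whose column is constant
  within a grouping's levels (the intercept always; any country-level
  covariate when regions coincide with countries), the likelihood is flat
  along the direction that trades the coefficient against the group
  intercepts, and a conjugate draw along that direction removes the random
  walk that otherwise makes group-level covariates mix very slowly;
* gamma updates for all precisions;
* the standard-normal deviate of each fixed-effect update is multiplied by
  the fixed sign of that column's inner product with the response. A
  symmetric deviate times a constant sign is still standard normal, so the
  posterior is untouched; this is what upgrades distributional sign
  equivariance to exact pathwise equivariance.

Default run length is 4 chains of 5000 iterations with 1000 burn-in
(pipeline utilities default to 2 chains of 2000 where they are run many
times). Convergence is monitored with split-$\hat R$ and an
autocorrelation-based effective sample size (Geyer initial monotone
sequence); fits with any fixed-effect $\hat R > 1.05$ are flagged and their
support claims suppressed. "Support" for an indicator means its 95%
equal-tailed credible interval excludes zero; no multiplicity correction is
applied, matching the per-indicator screening convention of this analysis
family, and the number of supported indicators is reported alongside.

The closed-form conjugate posterior (available when random effects are
disabled and the residual variance is fixed) is used as an independent
oracle in the tests, never as the implementation.

# Synthetic data and what passing tests mean

`simulate_panel()` generates, per country, indicator series with linear
drifts (cross-country drift SD 0.5, yearly noise SD 0.05) and, per
population, a wildlife trend

$$\theta_p = \textstyle\sum_k \beta_k z_{k,c(p)} + u_{s(p)} + u_{o(p)}
           + u_{r(p)} + e_p$$

where $z_k$ are the z-scored *oriented true* drifts, so the planted
$\beta_k$ are in exactly the units the pipeline reports. Abundance is
simulated around $\theta_p$ on the log10 scale (observation noise SD 0.1)
and exponentiated, so values are strictly positive; series lengths are
heterogeneous (default 8-18 years inside the window), and gap years are
removed only in the series interior so the span rules stay interpretable.
Random intercepts are drawn once and stored in the truth object together
with the per-country drifts and per-population trends.

Two generator choices deserve explanation:

* **Regions default to one per country** (`countries_per_region = 1`).
  The indicator effect is a country-level covariate; whatever cross-country
  heterogeneity the generator creates (including the contributions of the
  *other* planted indicators) must appear in the fitted model's
  random-effect structure for credible-interval calibration to be a
  meaningful target. With one region per country the generative process and
  the fitted model coincide exactly; with coarser regions (supported via
  the config) the fitted model is deliberately misspecified in the same way
  real analyses are, and CIs for country-level effects become optimistic.
  The package's calibration checks use the matched setting; the mismatched
  setting is available for sensitivity work.
* **Calibration experiments use many countries with few populations each**
  (40 countries of 10 populations in the shipped checks, >300 modelling
  rows per indicator). The effective sample size for a country-level
  coefficient is the number of countries, and the Gamma(1, 5e-5) precision
  prior — vague but proper — noticeably shrinks a variance component
  informed by only a dozen levels, which widens the gap between nominal and
  actual coverage. Cross-country replication, not within-country
  replication, is what buys calibrated uncertainty here; the package keeps
  the conventional prior and documents the degrees-of-freedom requirement
  rather than hiding it.

The generator does *not* attempt to mimic the real Living Planet Database's
taxonomic composition, the real World Bank value distributions, serially
correlated observation error, or nonlinear true trends. Passing recovery
tests therefore demonstrate that the chain — filters, homogenization,
orientation, regression — measures what it claims to measure under known
conditions; they say nothing about unmodelled features of real data (e.g.
density dependence, observer effects, or indicator revisions).

# Numerical and degenerate-input conventions

* Years are calendar integers; the annual change for year $t$ is
  value($t$) - value($t-1$).
* Spline basis dimension is floored at 3 (smallest cubic regression spline)
  and capped at $n_{\mathrm{obs}}$.
* Degenerate linear fits (zero variance in fitted or observed values) get
  $R^2 = 0$, never a negative or undefined value.
* Z-scoring refuses zero cross-country SD; assembly refuses missing values;
  the sampler refuses non-finite inputs and aborts on non-finite draws.
* Grouping factors with fewer than 2 levels are dropped from the model with
  a record in the fit object.
* All seeds derive deterministically from a single master seed (R's default
  RNG); two runs with the same config and seed are byte-identical, and
  per-fit seeds are drawn below 2^31.

# Problem sizes used in the shipped checks

The test suite runs the full pipeline on panels of 6-15 countries for the
unit and property tests, and the calibration check uses 40 replicates of a
40-country x 10-population, 3-indicator panel (planted effects 0.8, 0, -0.4)
with 2 chains of 1500 iterations per fit. The acceptance script repeats the
same computation with 30 replicates under a caller-supplied seed. These
sizes were chosen so each check exercises the statistical property it
targets (enough cross-country degrees of freedom, >300 rows per fit) while
a full run of everything stays comfortably within a coffee break on one
CPU.

# Known limitations

* Trend uncertainty is not propagated from the trend fits into the
  regression: only point trends are carried forward, as in the analysis
  family this package implements.
* The univariate screening deliberately leaves cross-indicator correlation
  on the table; with correlated indicators, a supported coefficient is a
  marginal association, not a partial effect.
* The marine/terrestrial distinction and country income classification are
  input metadata, not package logic.
* No Living-Planet-style index aggregation (geometric-mean chaining) is
  provided; the unit of analysis is the per-population trend.
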