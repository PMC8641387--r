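Package: devwild
Title: Cross-National Analysis of Human Development Indicators and Wildlife
    Abundance Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking change in country-level Sustainable Development
    Goal (SDG) indicators to wildlife population abundance trends. Implements
    the Living-Planet-style trend chain (linear models for short series,
    penalized-spline generalized additive models for longer ones, with
    R-squared and study-window quality filters), three-step homogenization of
    sparse country-by-indicator panels, indicator normalization and
    orientation, and univariate Bayesian hierarchical linear mixed models with
    species, taxonomic-order and region random intercepts fitted by a
    conjugate Gibbs sampler. Includes a synthetic-data generator with known
    ground truth for end-to-end parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
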