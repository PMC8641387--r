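#' Synthetic panel configuration
#'
#' Parameters of the synthetic-data generator, which emulates the two data
#' streams of the analysis: short, noisy, positive wildlife abundance series
#' with gaps and heterogeneous lengths, and country-level indicator series
#' with per-country linear drifts, linked by a planted cross-country linear
#' association between (z-scored) indicator trend and wildlife trend plus
#' species / taxonomic-order / region random intercepts.
#'
#' All trends live on the log10 scale per year. Defaults describe a
#' moderately noisy study: observation noise of 0.1 on log10 abundance,
#' indicator drifts with cross-country SD 0.5 and yearly noise 0.05, random
#' intercepts of SD 0.10--0.15 and a per-population residual trend SD of 0.1.
#'
#' @param n_countries,n_populations_per_country,n_indicators Panel dimensions.
#' @param study_start,study_end Calendar-year study window (default
#'   1996--2015); all generated series lie inside it.
#' @param series_length_range Inclusive range of abundance series lengths in
#'   years; lengths below 2 are rejected.
#' @param missing_prob Probability that an interior year of an abundance
#'   series is unobserved (first and last year are always kept, so span-based
#'   length rules stay interpretable).
#' @param obs_noise_sd SD of observation noise on log10 abundance.
#' @param indicator_noise_sd SD of yearly noise around each indicator's
#'   linear drift (on the transformed scale).
#' @param indicator_drift_sd Cross-country SD of the per-country indicator
#'   drift slopes.
#' @param beta_true Named vector mapping indicator code to the true
#'   cross-country effect, in response-trend units per 1 SD of (oriented)
#'   indicator trend. Defaults cycle 0.8, 0, -0.4, 0.3 over the indicators.
#' @param sigma_species,sigma_order,sigma_region SDs of the random
#'   intercepts (on the trend scale).
#' @param sigma_resid SD of the per-population residual trend.
#' @param countries_per_region Number of countries sharing one region label.
#'   The default 1 gives every country its own region, so the modelled
#'   random-intercept structure matches the generated cross-country
#'   heterogeneity exactly (the interpretable setting for calibration
#'   checks); larger values emulate the coarser regional groupings of real
#'   panels.
#' @param taxon_classes Character vector of taxon classes to generate; orders
#'   are allocated round-robin to classes.
#' @param log_required_codes,invert_codes,negative_codes Indicator codes
#'   flagged for log10 transform, for inversion (orientation flip), or
#'   generated with negative values (governance-index style).
#' @param mask Optional data frame (`country`, `indicator_code`) of series to
#'   withhold, emulating misaligned data gaps.
#' @param mask_prob Probability of withholding any (country, indicator)
#'   series at random (in addition to `mask`).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_countries = 10L, n_populations_per_country = 30L,
                         n_indicators = 3L,
                         study_start = 1996L, study_end = 2015L,
                         series_length_range = c(8L, 18L),
                         missing_prob = 0.1,
                         obs_noise_sd = 0.1,
                         indicator_noise_sd = 0.05,
                         indicator_drift_sd = 0.5,
                         beta_true = NULL,
                         sigma_species = 0.15, sigma_order = 0.10,
                         sigma_region = 0.10, sigma_resid = 0.1,
                         countries_per_region = 1L,
                         taxon_classes = c("bird", "mammal"),
                         log_required_codes = character(),
                         invert_codes = character(),
                         negative_codes = character(),
                         mask = NULL, mask_prob = 0,
                         seed = 1L) {
  window <- study_window(study_start, study_end)
  codes <- sprintf("ind%02d", seq_len(n_indicators))
  if (is.null(beta_true)) {
    beta_true <- stats::setNames(rep(c(0.8, 0, -0.4, 0.3),
                                     length.out = n_indicators), codes)
  }
  if (is.null(names(beta_true)) || !all(names(beta_true) %in% codes))
    stop("beta_true must be named by indicator codes ", paste(codes, collapse = ", "))
  beta <- stats::setNames(rep(0, n_indicators), codes)
  beta[names(beta_true)] <- beta_true
  if (length(series_length_range) != 2L || series_length_range[1L] < 2L)
    stop("series_length_range must allow lengths of at least 2 years")
  if (series_length_range[2L] > window$end - window$start + 1L)
    stop("series_length_range exceeds the study window")
  stopifnot(missing_prob >= 0, missing_prob <= 1, mask_prob >= 0, mask_prob <= 1,
            obs_noise_sd >= 0, indicator_noise_sd >= 0, indicator_drift_sd >= 0,
            sigma_species >= 0, sigma_order >= 0, sigma_region >= 0,
            sigma_resid >= 0, countries_per_region >= 1)
  structure(list(n_countries = as.integer(n_countries),
                 n_populations_per_country = as.integer(n_populations_per_country),
                 n_indicators = as.integer(n_indicators),
                 study_start = window$start, study_end = window$end,
                 series_length_range = as.integer(series_length_range),
                 missing_prob = missing_prob, obs_noise_sd = obs_noise_sd,
                 indicator_noise_sd = indicator_noise_sd,
                 indicator_drift_sd = indicator_drift_sd,
                 beta_true = beta,
                 sigma_species = sigma_species, sigma_order = sigma_order,
                 sigma_region = sigma_region, sigma_resid = sigma_resid,
                 countries_per_region = as.integer(countries_per_region),
                 taxon_classes = taxon_classes,
                 log_required_codes = log_required_codes,
                 invert_codes = invert_codes,
                 negative_codes = negative_codes,
                 mask = mask, mask_prob = mask_prob,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic abundance + indicator panel with known truth
#'
#' Draws per-country indicator series with linear drifts, z-scores the true
#' (oriented) drift slopes across countries, and plants each population's
#' wildlife trend as the linear combination of the indicator z-scores
#' weighted by `beta_true` plus species, order and region random intercepts
#' and a residual. Abundance is simulated on the log10 scale around that
#' trend and exponentiated, so values are strictly positive. Gap years are
#' removed only in the interior of each series.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_panel` with components `abundance`
#'   (population_id, binomial, order_name, region, country, taxon_class,
#'   year, value), `indicators` (country, indicator_code, year, value),
#'   `indicator_meta` (indicator_code, log_required, invert), `country_meta`
#'   (country, region, land_area_km2, hpd_1996, income_class_1995), `truth`
#'   (planted effects, realized random intercepts, true per-country indicator
#'   trends and z-scores, true per-population wildlife trends) and `config`.
#' @export
simulate_panel <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nC <- cfg$n_countries
  codes <- names(cfg$beta_true)
  countries <- sprintf("C%02d", seq_len(nC))
  n_regions <- max(2L, ceiling(nC / cfg$countries_per_region))
  regions <- sprintf("RG%d", seq_len(n_regions))
  country_region <- stats::setNames(
    rep(regions, each = cfg$countries_per_region, length.out = nC), countries)

  country_meta <- data.frame(
    country = countries,
    region = unname(country_region),
    land_area_km2 = stats::rlnorm(nC, meanlog = log(3e5), sdlog = 1),
    hpd_1996 = stats::rlnorm(nC, meanlog = log(50), sdlog = 0.7),
    income_class_1995 = rep(c("low", "lower-middle"), length.out = nC),
    stringsAsFactors = FALSE)

  years <- cfg$study_start:cfg$study_end
  nY <- length(years)

  # indicator drifts: true per-country trend on the transformed (analysis) scale
  drift <- matrix(stats::rnorm(nC * length(codes), 0, cfg$indicator_drift_sd),
                  nrow = nC, dimnames = list(countries, codes))
  level <- matrix(stats::rnorm(nC * length(codes), 10, 2),
                  nrow = nC, dimnames = list(countries, codes))

  ind_rows <- vector("list", nC * length(codes))
  r <- 0L
  for (code in codes) {
    logreq <- code %in% cfg$log_required_codes
    negoff <- code %in% cfg$negative_codes
    base <- level[, code]
    if (negoff) base <- base - mean(base) # roughly half the values go negative
    if (logreq) base <- abs(base) / 5 + 1 # modest positive log10-level
    for (ci in seq_len(nC)) {
      mu <- base[ci] + drift[ci, code] * (years - cfg$study_start)
      v <- mu + stats::rnorm(nY, 0, cfg$indicator_noise_sd)
      if (logreq) v <- 10^v
      r <- r + 1L
      ind_rows[[r]] <- data.frame(country = countries[ci],
                                  indicator_code = code, year = years,
                                  value = v, stringsAsFactors = FALSE)
    }
  }
  indicators <- do.call(rbind, ind_rows)

  # masking of whole (country, indicator) series
  keep <- rep(TRUE, nrow(indicators))
  if (cfg$mask_prob > 0) {
    cells <- unique(indicators[, c("country", "indicator_code")])
    drop <- cells[stats::runif(nrow(cells)) < cfg$mask_prob, , drop = FALSE]
    if (nrow(drop)) {
      key <- paste(indicators$country, indicators$indicator_code)
      keep <- keep & !(key %in% paste(drop$country, drop$indicator_code))
    }
  }
  if (!is.null(cfg$mask) && nrow(cfg$mask)) {
    key <- paste(indicators$country, indicators$indicator_code)
    keep <- keep & !(key %in% paste(cfg$mask$country, cfg$mask$indicator_code))
  }
  indicators <- indicators[keep, , drop = FALSE]
  rownames(indicators) <- NULL

  indicator_meta <- data.frame(
    indicator_code = codes,
    log_required = codes %in% cfg$log_required_codes,
    invert = codes %in% cfg$invert_codes,
    stringsAsFactors = FALSE)

  # oriented, z-scored true indicator trends (sample-SD convention)
  orient <- ifelse(codes %in% cfg$invert_codes, -1, 1)
  z_true <- sweep(drift, 2L, orient, `*`)
  z_true <- scale(z_true)[, , drop = FALSE]
  dimnames(z_true) <- list(countries, codes)

  # taxonomy: species pool, orders round-robin over taxon classes
  nPop <- nC * cfg$n_populations_per_country
  n_species <- max(2L, round(nPop * 0.6))
  n_orders <- max(2L, min(12L, 6L * length(cfg$taxon_classes)))
  species_pool <- sprintf("Genus sp%03d", seq_len(n_species))
  order_pool <- sprintf("Order%02d", seq_len(n_orders))
  order_class <- stats::setNames(rep(cfg$taxon_classes, length.out = n_orders),
                                 order_pool)
  species_order <- stats::setNames(rep(order_pool, length.out = n_species),
                                   species_pool)
  u_species <- stats::setNames(stats::rnorm(n_species, 0, cfg$sigma_species),
                               species_pool)
  u_order <- stats::setNames(stats::rnorm(n_orders, 0, cfg$sigma_order),
                             order_pool)
  u_region <- stats::setNames(stats::rnorm(n_regions, 0, cfg$sigma_region),
                              regions)

  pop_country <- rep(countries, each = cfg$n_populations_per_country)
  pop_id <- sprintf("P%04d", seq_len(nPop))
  pop_species <- sample(species_pool, nPop, replace = TRUE)
  pop_order <- unname(species_order[pop_species])
  pop_region <- unname(country_region[pop_country])
  pop_class <- unname(order_class[pop_order])

  planted <- as.numeric(z_true[pop_country, codes, drop = FALSE] %*%
                          cfg$beta_true[codes])
  pop_trend <- planted + u_species[pop_species] + u_order[pop_order] +
    u_region[pop_region] + stats::rnorm(nPop, 0, cfg$sigma_resid)
  pop_trend <- unname(pop_trend)

  lo <- cfg$series_length_range[1L]; hi <- cfg$series_length_range[2L]
  ab_rows <- vector("list", nPop)
  for (p in seq_len(nPop)) {
    L <- sample(lo:hi, 1L)
    first <- cfg$study_start +
      sample.int(cfg$study_end - cfg$study_start + 2L - L, 1L) - 1L
    yrs <- first:(first + L - 1L)
    if (L > 2L && cfg$missing_prob > 0) {
      interior <- yrs[-c(1L, L)]
      yrs <- sort(c(yrs[c(1L, L)],
                    interior[stats::runif(length(interior)) >= cfg$missing_prob]))
    }
    a0 <- stats::rnorm(1L, 2, 0.5)
    logN <- a0 + pop_trend[p] * (yrs - yrs[1L]) +
      stats::rnorm(length(yrs), 0, cfg$obs_noise_sd)
    ab_rows[[p]] <- data.frame(population_id = pop_id[p],
                               binomial = pop_species[p],
                               order_name = pop_order[p],
                               region = pop_region[p],
                               country = pop_country[p],
                               taxon_class = pop_class[p],
                               year = yrs, value = 10^logN,
                               stringsAsFactors = FALSE)
  }
  abundance <- do.call(rbind, ab_rows)
  rownames(abundance) <- NULL

  truth <- list(
    beta_true = as.list(cfg$beta_true),
    intercepts = list(species = as.list(u_species),
                      order = as.list(u_order),
                      region = as.list(u_region)),
    indicator_trends = drift,
    indicator_z = z_true,
    population_trends = stats::setNames(pop_trend, pop_id),
    assignments = data.frame(population_id = pop_id, binomial = pop_species,
                             order_name = pop_order, region = pop_region,
                             country = pop_country, taxon_class = pop_class,
                             stringsAsFactors = FALSE))

  structure(list(abundance = abundance, indicators = indicators,
                 indicator_meta = indicator_meta, country_meta = country_meta,
                 truth = truth, config = cfg),
            class = "synth_panel")
}

#' @export
print.synth_panel <- function(x, ...) {
  cat(sprintf(paste0("synthetic panel: %d populations in %d countries, ",
                     "%d indicators, window %d-%d (seed %d)\n"),
              length(unique(x$abundance$population_id)),
              x$config$n_countries, x$config$n_indicators,
              x$config$study_start, x$config$study_end, x$config$seed))
  invisible(x)
}

#' Write a synthetic panel to CSV/JSON files
#'
#' Writes `abundance.csv`, `indicators.csv`, `country_meta.csv` and
#' `truth.json` into a directory, the on-disk interface consumed by the rest
#' of the pipeline (user-supplied data of identical schema works the same
#' way).
#'
#' @param panel A [simulate_panel()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synth_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(panel$abundance, file.path(dir, "abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(panel$indicators, file.path(dir, "indicators.csv"),
                   row.names = FALSE)
  utils::write.csv(panel$indicator_meta, file.path(dir, "indicator_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(panel$country_meta, file.path(dir, "country_meta.csv"),
                   row.names = FALSE)
  truth <- panel$truth
  truth$indicator_trends <- as.data.frame(truth$indicator_trends)
  truth$indicator_z <- as.data.frame(truth$indicator_z)
  truth$population_trends <- as.list(truth$population_trends)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a panel directory
#'
#' Reads the CSV/JSON files written by [write_panel()] — or user-supplied
#' files of identical schema — back into the in-memory panel structure
#' accepted by [run_pipeline()]. `truth.json` and `indicator_meta.csv` are
#' optional; absent indicator metadata defaults to no log transforms and no
#' inversions.
#'
#' @param dir Directory containing `abundance.csv`, `indicators.csv`,
#'   `country_meta.csv` and optionally `indicator_meta.csv`, `truth.json`.
#' @return A list with components `abundance`, `indicators`,
#'   `indicator_meta`, `country_meta` and (when present) `truth`.
#' @export
read_panel <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  for (f in c("abundance.csv", "indicators.csv", "country_meta.csv"))
    if (!file.exists(file.path(dir, f))) stop("missing input file: ", f)
  abundance <- rd("abundance.csv")
  indicators <- rd("indicators.csv")
  country_meta <- rd("country_meta.csv")
  meta_path <- file.path(dir, "indicator_meta.csv")
  indicator_meta <- if (file.exists(meta_path)) rd("indicator_meta.csv")
  else data.frame(indicator_code = sort(unique(indicators$indicator_code)),
                  log_required = FALSE, invert = FALSE,
                  stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = FALSE)
  list(abundance = abundance, indicators = indicators,
       indicator_meta = indicator_meta, country_meta = country_meta,
       truth = truth)
}
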