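test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_countries = 4, n_populations_per_country = 3,
                      n_indicators = 2, seed = 42)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$abundance, p2$abundance)
  expect_identical(p1$indicators, p2$indicators)
  expect_identical(p1$country_meta, p2$country_meta)
  expect_identical(p1$truth, p2$truth)
  # serialized output is byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  write_panel(p1, d1); write_panel(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("panel obeys its structural invariants", {
  cfg <- synth_config(n_countries = 5, n_populations_per_country = 4,
                      n_indicators = 3, missing_prob = 0.3, seed = 9)
  p <- simulate_panel(cfg)
  expect_true(all(p$abundance$value > 0))
  ids <- unique(p$abundance$population_id)
  # every population appears exactly once in the truth
  expect_setequal(names(p$truth$population_trends), ids)
  expect_identical(sort(p$truth$assignments$population_id), sort(ids))
  for (id in ids) {
    yrs <- p$abundance$year[p$abundance$population_id == id]
    L <- max(yrs) - min(yrs) + 1L
    # span within the configured length range, first/last never removed
    expect_gte(L, cfg$series_length_range[1])
    expect_lte(L, cfg$series_length_range[2])
    expect_gte(min(yrs), cfg$study_start)
    expect_lte(max(yrs), cfg$study_end)
    expect_gte(length(yrs), 2L)
  }
  # masking disabled: full country x indicator coverage
  cells <- unique(p$indicators[, c("country", "indicator_code")])
  expect_identical(nrow(cells), 5L * 3L)
})

test_that("planted trends are exactly recoverable when noise is zero", {
  cfg <- synth_config(n_countries = 6, n_populations_per_country = 4,
                      n_indicators = 1, beta_true = c(ind01 = 0.5),
                      obs_noise_sd = 0, indicator_noise_sd = 0,
                      sigma_species = 0, sigma_order = 0, sigma_region = 0,
                      sigma_resid = 0, missing_prob = 0, seed = 5)
  p <- simulate_panel(cfg)
  for (id in unique(p$abundance$population_id)) {
    s <- p$abundance[p$abundance$population_id == id, ]
    slope <- unname(coef(lm(log10(s$value) ~ s$year))[2])
    ct <- s$country[1]
    expect_equal(slope, 0.5 * p$truth$indicator_z[ct, "ind01"],
                 tolerance = 1e-10)
    expect_equal(slope, unname(p$truth$population_trends[id]),
                 tolerance = 1e-10)
  }
  # indicator OLS slopes equal the true drifts exactly
  for (ct in unique(p$indicators$country)) {
    s <- p$indicators[p$indicators$country == ct, ]
    slope <- unname(coef(lm(s$value ~ s$year))[2])
    expect_equal(slope, p$truth$indicator_trends[ct, "ind01"],
                 tolerance = 1e-10)
  }
})

test_that("zero-effect case leaves only group intercepts in the slope", {
  cfg <- synth_config(n_countries = 4, n_populations_per_country = 3,
                      n_indicators = 1, beta_true = c(ind01 = 0),
                      obs_noise_sd = 0, indicator_noise_sd = 0,
                      sigma_resid = 0, missing_prob = 0, seed = 13)
  p <- simulate_panel(cfg)
  tr <- p$truth
  asn <- tr$assignments
  for (i in seq_len(nrow(asn))) {
    expected <- tr$intercepts$species[[asn$binomial[i]]] +
      tr$intercepts$order[[asn$order_name[i]]] +
      tr$intercepts$region[[asn$region[i]]]
    expect_equal(unname(tr$population_trends[asn$population_id[i]]), expected,
                 tolerance = 1e-12)
    s <- p$abundance[p$abundance$population_id == asn$population_id[i], ]
    slope <- unname(coef(lm(log10(s$value) ~ s$year))[2])
    expect_equal(slope, expected, tolerance = 1e-10)
  }
})

test_that("flags produce governance-style and monetary-style indicators", {
  cfg <- synth_config(n_countries = 6, n_populations_per_country = 2,
                      n_indicators = 3,
                      negative_codes = "ind02", log_required_codes = "ind03",
                      seed = 21)
  p <- simulate_panel(cfg)
  v2 <- p$indicators$value[p$indicators$indicator_code == "ind02"]
  expect_lt(min(v2), 0)
  v3 <- p$indicators$value[p$indicators$indicator_code == "ind03"]
  expect_true(all(v3 > 0))
  expect_true(p$indicator_meta$log_required[
    p$indicator_meta$indicator_code == "ind03"])
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(series_length_range = c(1, 5)), "at least 2")
  expect_error(synth_config(series_length_range = c(5, 40)), "study window")
  expect_error(synth_config(study_start = 2000, study_end = 1999), "start < end")
  expect_error(synth_config(missing_prob = 1.2))
  expect_error(synth_config(obs_noise_sd = -1))
  expect_error(synth_config(beta_true = c(bad = 1)), "named by indicator codes")
})

test_that("a written panel reads back into an equivalent structure", {
  p <- simulate_panel(synth_config(n_countries = 3,
                                   n_populations_per_country = 2,
                                   n_indicators = 2, seed = 8))
  d <- tempfile()
  write_panel(p, d)
  q <- read_panel(d)
  expect_equal(q$abundance, p$abundance)
  expect_equal(q$indicators, p$indicators)
  expect_equal(q$indicator_meta, p$indicator_meta)
  expect_equal(q$country_meta, p$country_meta)
  expect_equal(unlist(q$truth$beta_true), unlist(p$truth$beta_true))
  unlink(d, recursive = TRUE)
})

test_that("zero-noise panels pass the trend chain with 100% retention", {
  cfg <- synth_config(n_countries = 4, n_populations_per_country = 5,
                      n_indicators = 2, beta_true = c(ind01 = 0.3, ind02 = 0),
                      obs_noise_sd = 0, indicator_noise_sd = 0,
                      missing_prob = 0.2, seed = 31)
  p <- simulate_panel(cfg)
  wt <- wildlife_trends(p$abundance)
  expect_true(all(wt$trends$retained))
  it <- indicator_trends(p$indicators, p$indicator_meta)
  expect_true(all(it$trends$retained))
})
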