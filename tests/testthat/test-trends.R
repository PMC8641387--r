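test_that("abundance and indicator transforms follow the stated rules", {
  expect_equal(log_abundance(c(10, 100, 1000)), c(1, 2, 3))
  # zero replaced by 1% of the series mean before logging
  expect_equal(log_abundance(c(0, 10)), c(log10(0.05), 1))
  expect_error(log_abundance(c(0, 0, 0)), "all-zero")
  expect_error(log_abundance(c(-1, 2)), "nonnegative")

  # cross-country minimum maps to shift_eps
  expect_equal(transform_indicator(-2, cross_min = -2, shift_eps = 0.01), 0.01)
  expect_equal(transform_indicator(c(1, 5), cross_min = -2, shift_eps = 0.01),
               c(3.01, 7.01))
  # identity when no negatives and no log flag
  expect_equal(transform_indicator(c(1, 5), cross_min = 1), c(1, 5))
  # monetary indicators are log10-transformed after the positive shift
  expect_equal(transform_indicator(c(10, 100), log_required = TRUE,
                                   cross_min = 10), c(1, 2))
  expect_error(transform_indicator(0, log_required = TRUE, cross_min = 1),
               "nonpositive")
})

test_that("linear path reproduces a noiseless line exactly", {
  yrs <- 2000:2004
  ft <- fit_trend(yrs, 1 + 0.2 * (yrs - 2000))
  expect_identical(ft$method, "linear")
  expect_equal(ft$r_squared, 1)
  expect_equal(unname(ft$annual_changes), rep(0.2, 4), tolerance = 1e-12)
  expect_equal(ft$mean_trend, 0.2, tolerance = 1e-12)
  expect_true(ft$retained)
})

test_that("the observation-count boundary switches linear to GAM at 6", {
  yrs5 <- 2000:2004; yrs6 <- 2000:2005
  expect_identical(fit_trend(yrs5, rnorm(5))$method, "linear")
  expect_identical(fit_trend(yrs6, 1 + 0.1 * (0:5))$method, "gam")
})

test_that("GAM path reproduces a noiseless line to spline precision", {
  yrs <- 1996:2015
  ft <- fit_trend(yrs, 3 + 0.1 * (yrs - 1996))
  expect_identical(ft$method, "gam")
  expect_true(all(abs(ft$annual_changes - 0.1) < 1e-3))
  expect_equal(ft$mean_trend, 0.1, tolerance = 1e-3)
})

test_that("constant series get R-squared 0 and a distinct rejection reason", {
  ft <- fit_trend(2000:2009, rep(3, 10))
  expect_equal(ft$r_squared, 0)
  expect_equal(unname(ft$annual_changes), rep(0, length(ft$annual_changes)))
  expect_false(ft$retained)
  expect_identical(ft$rejection_reason, "constant_series")
  expect_true(is.na(ft$mean_trend))
})

test_that("gap years are filled by linear interpolation on the linear path", {
  ft <- fit_trend(c(2000, 2002, 2004), c(1, 2, 3))
  expect_equal(unname(ft$annual_changes), rep(0.5, 4), tolerance = 1e-12)
})

test_that("linear-path value source is configurable and telescopes", {
  set.seed(42)
  yrs <- 2001:2005
  y <- 1 + 0.3 * (yrs - 2001) + rnorm(5, 0, 0.05)
  # fitted source: mean annual change telescopes to the OLS slope
  cf <- trend_config(linear_changes_from = "fitted")
  ft <- fit_trend(yrs, y, config = cf)
  slope <- unname(coef(lm(y ~ yrs))[2])
  expect_equal(mean(ft$annual_changes), slope, tolerance = 1e-12)
  # interpolated source: telescopes to the endpoint difference over the span
  fi <- fit_trend(yrs, y, config = trend_config())
  expect_equal(mean(fi$annual_changes), (y[5] - y[1]) / 4, tolerance = 1e-12)
})

test_that("annual changes are shift-invariant and scale-equivariant (linear path)", {
  set.seed(7)
  yrs <- 2000:2004
  y <- 2 + 0.15 * (yrs - 2000) + rnorm(5, 0, 0.03)
  base <- fit_trend(yrs, y)
  shifted <- fit_trend(yrs, y + 5)
  expect_equal(shifted$annual_changes, base$annual_changes, tolerance = 1e-12)
  scaled <- fit_trend(yrs, y * 3)
  expect_equal(scaled$mean_trend, base$mean_trend * 3, tolerance = 1e-12)
})

test_that("annual changes are clipped to the study window", {
  # observed 1995-2000 with a gap: changes at 1996..2000, but the 1996 change
  # covers 1995->1996 which is outside the window, so 1997..2000 remain
  ft <- fit_trend(c(1995, 1996, 1997, 1999, 2000), 1 + 0.2 * c(0, 1, 2, 4, 5))
  expect_identical(as.integer(names(ft$annual_changes)), 1997:2000)
  expect_equal(ft$span_years, 5L)
  expect_true(ft$retained)
})

test_that("retention is monotone in the R-squared threshold", {
  set.seed(11)
  for (i in 1:20) {
    yrs <- 2000:2007
    y <- 0.2 * (yrs - 2000) + rnorm(8, 0, runif(1, 0, 1.5))
    ft <- fit_trend(yrs, y)
    strict <- retain_trend(ft$r_squared, ft$span_years, r2_min = 0.7)
    loose <- retain_trend(ft$r_squared, ft$span_years, r2_min = 0.3)
    expect_true(!strict || loose)  # lowering the threshold never removes
  }
})

test_that("fit_trend rejects degenerate inputs", {
  expect_error(fit_trend(2000, 1), "two observations")
  expect_error(fit_trend(c(2000, 2000), c(1, 2)), "strictly increasing")
  expect_error(fit_trend(2000:2002, c(1, NA, 2)), "finite")
})

test_that("batch_trends captures per-series failures and counts", {
  empty <- batch_trends(as_series(character(), integer(), numeric()))
  expect_identical(nrow(empty$trends), 0L)

  yrs <- 2000:2007
  good <- as_series("a", yrs, 1 + 0.5 * (yrs - 2000))
  noisy_y <- 0.05 * (yrs - 2000) + c(2, -2, 2, -2, 2, -2, 2, -2)
  # verify by direct computation that the noisy series fails the R2 rule
  stopifnot(summary(lm(noisy_y ~ yrs))$r.squared < 0.5)
  noisy <- as_series("b", yrs, noisy_y)
  short <- as_series("c", 2000L, 1)
  bt <- batch_trends(rbind(good, noisy, short))
  expect_identical(sum(bt$trends$retained), 1L)
  expect_identical(bt$trends$rejection_reason[bt$trends$series_id == "b"],
                   "low_r2")
  expect_identical(bt$trends$rejection_reason[bt$trends$series_id == "c"],
                   "too_short")
})

test_that("wildlife_trends validates inputs and joins taxonomy labels", {
  ab <- data.frame(
    population_id = rep(c("P1", "P2", "P3"), times = c(6, 3, 2)),
    binomial = "Sp a", order_name = "O1", region = "R1", country = "C1",
    taxon_class = "bird",
    year = c(2000:2005, 2000:2002, c(2000, 2001)),
    value = c(10 * 1.3^(0:5), c(5, 6, 7), c(1, 2)),
    stringsAsFactors = FALSE)
  wt <- wildlife_trends(ab)
  tr <- wt$trends
  expect_identical(tr$rejection_reason[tr$population_id == "P2"], "too_short")
  expect_identical(tr$rejection_reason[tr$population_id == "P3"], "too_short")
  expect_true(tr$retained[tr$population_id == "P1"])
  expect_identical(tr$country[tr$population_id == "P1"], "C1")
  # the retained trend is on the log10 scale
  expect_equal(tr$mean_trend[tr$population_id == "P1"], log10(1.3),
               tolerance = 1e-6)
})

test_that("indicator_trends applies a shared cross-country shift", {
  ind <- rbind(
    data.frame(country = "C1", indicator_code = "g1", year = 2000:2006,
               value = -2 + 0.5 * (0:6)),
    data.frame(country = "C2", indicator_code = "g1", year = 2000:2006,
               value = 1 + 0.25 * (0:6)))
  meta <- data.frame(indicator_code = "g1", log_required = FALSE,
                     invert = FALSE)
  it <- indicator_trends(ind, meta)
  tr <- it$trends
  # the shift is a constant, so trends equal the raw slopes
  expect_equal(tr$mean_trend[tr$country == "C1"], 0.5, tolerance = 1e-9)
  expect_equal(tr$mean_trend[tr$country == "C2"], 0.25, tolerance = 1e-9)
})
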