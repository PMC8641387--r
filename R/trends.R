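#' Study window
#'
#' The calendar-year window over which annual changes are retained and
#' averaged into a trend. Defaults to 1996--2015.
#'
#' @param start,end First and last calendar year of the window.
#' @return A list with integer components `start` and `end`.
#' @export
study_window <- function(start = 1996L, end = 2015L) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single years")
  if (start >= end) stop("study window must satisfy start < end")
  list(start = start, end = end)
}

#' Trend-chain configuration
#'
#' Tunable parameters of the trend chain. Defaults reproduce the standard
#' Living-Planet-style settings: linear fits below 6 observations, a
#' penalized cubic regression spline with basis dimension `ceil(n/2)` from 6
#' observations up, retention of series with R-squared above 0.5 and at least
#' 5 years of annual-change span inside the study window.
#'
#' @param r2_min Retention threshold on R-squared; strict (`>`).
#' @param min_span Minimum span in years (inclusive of both interval
#'   endpoints) of window-clipped annual changes for retention.
#' @param gam_min_obs Observation count at and above which the GAM path is
#'   used instead of ordinary least squares.
#' @param zero_replace_frac Zeros in abundance series are replaced by this
#'   fraction of the mean of the nonzero values before taking log10.
#' @param shift_eps After shift-centering an indicator that contains negative
#'   values, its cross-country minimum maps to this small positive value.
#' @param linear_changes_from For the linear path, whether annual changes are
#'   differences of the observed/interpolated series (`"interpolated"`) or of
#'   the fitted regression line (`"fitted"`). The linear model is always the
#'   fit-quality gate.
#' @param k_fun Function mapping observation count to the spline basis
#'   dimension; default `ceiling(n/2)` (floored at 3, the smallest cubic
#'   regression spline basis).
#' @param sd_type `"sample"` (n-1 denominator) or `"population"` SD for
#'   downstream z-scoring.
#' @return A list of class `trend_config`.
#' @export
trend_config <- function(r2_min = 0.5, min_span = 5L, gam_min_obs = 6L,
                         zero_replace_frac = 0.01, shift_eps = 0.01,
                         linear_changes_from = c("interpolated", "fitted"),
                         k_fun = function(n) ceiling(n / 2),
                         sd_type = c("sample", "population")) {
  linear_changes_from <- match.arg(linear_changes_from)
  sd_type <- match.arg(sd_type)
  stopifnot(r2_min >= 0, min_span >= 1, gam_min_obs >= 3,
            zero_replace_frac > 0, shift_eps > 0)
  structure(list(r2_min = r2_min, min_span = as.integer(min_span),
                 gam_min_obs = as.integer(gam_min_obs),
                 zero_replace_frac = zero_replace_frac,
                 shift_eps = shift_eps,
                 linear_changes_from = linear_changes_from,
                 k_fun = k_fun, sd_type = sd_type),
            class = "trend_config")
}

#' Log-transform an abundance series
#'
#' Abundance values are log10-transformed. Zeros are first replaced by
#' `zero_replace_frac` times the mean of the series (the usual
#' Living-Planet-Index convention for zero counts); an all-zero series cannot
#' be placed on the log scale and is rejected.
#'
#' @param values Nonnegative abundance values.
#' @param zero_replace_frac Replacement fraction for zeros.
#' @return log10-transformed values.
#' @export
log_abundance <- function(values, zero_replace_frac = 0.01) {
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and nonnegative")
  if (all(values == 0)) stop("all-zero abundance series cannot be log-transformed")
  values[values == 0] <- zero_replace_frac * mean(values)
  log10(values)
}

#' Transform an indicator series
#'
#' Applies the indicator preprocessing: series of an indicator whose values go
#' negative anywhere across countries are shift-centered to a positive range
#' (value minus the cross-country minimum, plus `shift_eps`), and indicators
#' with monetary or population-size units (`log_required`) are then
#' log10-transformed. The cross-country minimum must be supplied so that every
#' country's series of the same indicator receives the identical shift.
#'
#' @param values Indicator values for one country.
#' @param log_required Whether the indicator is log10-transformed.
#' @param cross_min Minimum of the indicator's values across all countries.
#' @param shift_eps Small positive value the cross-country minimum maps to.
#' @return Transformed values.
#' @export
transform_indicator <- function(values, log_required = FALSE, cross_min = 0,
                                shift_eps = 0.01) {
  if (any(!is.finite(values))) stop("indicator values must be finite")
  if (cross_min < 0 || (log_required && cross_min <= 0))
    values <- values - cross_min + shift_eps
  if (log_required) {
    if (any(values <= 0))
      stop("log-transform of nonpositive indicator values; check cross_min")
    values <- log10(values)
  }
  values
}

#' Trend retention rule
#'
#' A fitted trend is retained when the model fit is good (R-squared strictly
#' greater than `r2_min`) and the window-clipped annual changes span at least
#' `min_span` years (counting both endpoints of the covered interval).
#'
#' @param r_squared Goodness of fit in `[0, 1]`.
#' @param span_years Years spanned by the window-clipped annual changes.
#' @param r2_min,min_span Thresholds; see [trend_config()].
#' @return Logical.
#' @export
retain_trend <- function(r_squared, span_years, r2_min = 0.5, min_span = 5) {
  !is.na(r_squared) && r_squared > r2_min && span_years >= min_span
}

# Clip annual changes (named by the year they end in) to the window: the
# change for year t covers t-1 -> t, so both t-1 and t must lie inside.
.clip_changes <- function(changes, window) {
  yrs <- as.integer(names(changes))
  changes[yrs - 1L >= window$start & yrs <= window$end]
}

.span_years <- function(changes) {
  if (length(changes) == 0L) return(0L)
  yrs <- as.integer(names(changes))
  max(yrs) - (min(yrs) - 1L) + 1L
}

#' Fit the trend chain to one yearly series
#'
#' Converts one (already transformed) yearly series into a mean-annual-change
#' trend. Series with fewer than `gam_min_obs` observations are fitted by
#' ordinary least squares of value on year, with gap years filled by linear
#' interpolation; longer series are fitted by a penalized cubic regression
#' spline (`mgcv::gam`, basis dimension `k_fun(n_obs)`) and predicted at every
#' integer year of the observed span. Annual changes are consecutive
#' differences of the yearly values, clipped to the study window; R-squared is
#' the squared Pearson correlation between fitted and observed values at the
#' observed years (defined as 0 for degenerate constant fits). The trend is
#' the arithmetic mean of the retained annual changes, reported only when the
#' retention rule passes.
#'
#' @param years Strictly increasing integer calendar years (at least 2).
#' @param values Transformed series values, same length as `years`.
#' @param window A [study_window()].
#' @param config A [trend_config()].
#' @param series_id Optional identifier carried into the result.
#' @return An object of class `trend_fit`: a list with `series_id`, `method`
#'   (`"linear"` or `"gam"`), `n_obs`, `r_squared`, `annual_changes` (named by
#'   the year each change ends in, window-clipped), `span_years`,
#'   `mean_trend` (NA unless retained), `retained`, `rejection_reason`.
#' @export
fit_trend <- function(years, values, window = study_window(),
                      config = trend_config(), series_id = NA_character_) {
  years <- as.integer(years)
  n <- length(years)
  if (n < 2L) stop("at least two observations are required")
  if (length(values) != n) stop("years and values must have equal length")
  if (any(diff(years) <= 0L)) stop("years must be strictly increasing")
  if (any(!is.finite(values))) stop("series values must be finite")

  yr_all <- seq(min(years), max(years))
  constant <- isTRUE(all(values == values[1L]))

  if (n < config$gam_min_obs) {
    method <- "linear"
    fit <- stats::lm(values ~ years)
    fitted_obs <- stats::fitted(fit)
    if (config$linear_changes_from == "fitted") {
      yearly <- stats::predict(fit, newdata = data.frame(years = yr_all))
    } else {
      filled <- rep(NA_real_, length(yr_all))
      filled[match(years, yr_all)] <- values
      yearly <- zoo::na.approx(zoo::zoo(filled, yr_all))
      yearly <- as.numeric(yearly)
    }
  } else {
    method <- "gam"
    k <- max(3L, min(n, as.integer(config$k_fun(n))))
    dat <- data.frame(year = years, value = values)
    fit <- mgcv::gam(value ~ s(year, k = k, bs = "cr"), data = dat)
    fitted_obs <- stats::fitted(fit)
    yearly <- as.numeric(stats::predict(fit, newdata = data.frame(year = yr_all)))
  }

  r2 <- if (constant || stats::sd(values) == 0 || stats::sd(fitted_obs) == 0) {
    0
  } else {
    max(0, stats::cor(fitted_obs, values)^2)
  }

  changes <- diff(yearly)
  names(changes) <- yr_all[-1L]
  changes <- .clip_changes(changes, window)
  span <- .span_years(changes)

  retained <- retain_trend(r2, span, config$r2_min, config$min_span)
  reason <- if (retained) NA_character_
  else if (constant) "constant_series"
  else if (span < config$min_span) "insufficient_window_overlap"
  else "low_r2"

  structure(list(series_id = series_id, method = method, n_obs = n,
                 r_squared = r2, annual_changes = changes,
                 span_years = span,
                 mean_trend = if (retained) mean(changes) else NA_real_,
                 retained = retained, rejection_reason = reason),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit [%s]: %s, n_obs = %d, R^2 = %.3f, %s\n",
              x$series_id, x$method, x$n_obs, x$r_squared,
              if (x$retained) sprintf("mean trend = %.4g / yr", x$mean_trend)
              else sprintf("rejected (%s)", x$rejection_reason)))
  invisible(x)
}

#' Fit the trend chain to a batch of series
#'
#' Applies [fit_trend()] to every series in a long table. Per-series failures
#' (too few observations, non-finite values) are captured as rejections, never
#' raised.
#'
#' @param series Data frame with columns `series_id`, `year`, `value`
#'   (values already transformed).
#' @param window A [study_window()].
#' @param config A [trend_config()].
#' @return A list with `trends` (one row per series: `series_id`, `method`,
#'   `n_obs`, `r_squared`, `mean_trend`, `retained`, `rejection_reason`) and
#'   `fits` (the `trend_fit` objects, named by series id).
#' @export
batch_trends <- function(series, window = study_window(),
                         config = trend_config()) {
  stopifnot(all(c("series_id", "year", "value") %in% names(series)))
  ids <- unique(series$series_id)
  fits <- vector("list", length(ids))
  names(fits) <- ids
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- series[series$series_id == ids[i], , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    ft <- tryCatch(
      fit_trend(s$year, s$value, window, config, series_id = ids[i]),
      error = function(e) {
        structure(list(series_id = ids[i], method = NA_character_,
                       n_obs = nrow(s), r_squared = NA_real_,
                       annual_changes = numeric(), span_years = 0L,
                       mean_trend = NA_real_, retained = FALSE,
                       rejection_reason = if (nrow(s) < 2L) "too_short"
                                          else paste0("fit_error: ", conditionMessage(e))),
                  class = "trend_fit")
      })
    fits[[i]] <- ft
    rows[[i]] <- data.frame(series_id = ids[i], method = ft$method,
                            n_obs = ft$n_obs, r_squared = ft$r_squared,
                            mean_trend = ft$mean_trend, retained = ft$retained,
                            rejection_reason = ft$rejection_reason,
                            stringsAsFactors = FALSE)
  }
  trends <- if (length(rows)) do.call(rbind, rows)
  else data.frame(series_id = character(), method = character(),
                  n_obs = integer(), r_squared = numeric(),
                  mean_trend = numeric(), retained = logical(),
                  rejection_reason = character(), stringsAsFactors = FALSE)
  list(trends = trends, fits = fits)
}

#' Wildlife abundance trends
#'
#' Runs the trend chain over a long abundance table. Each population's values
#' are log10-transformed (with zero replacement, see [log_abundance()]) before
#' fitting; populations violating the input rules (fewer than 2 observations,
#' observed span under `min_span` years, all-zero series) are rejected with a
#' machine-readable reason.
#'
#' @param abundance Data frame with columns `population_id`, `binomial`,
#'   `order_name`, `region`, `country`, `taxon_class`, `year`, `value`.
#' @param window A [study_window()].
#' @param config A [trend_config()].
#' @return A list with `trends` (the batch table joined with the taxonomy /
#'   geography labels) and `fits`.
#' @export
wildlife_trends <- function(abundance, window = study_window(),
                            config = trend_config()) {
  need <- c("population_id", "binomial", "order_name", "region", "country",
            "taxon_class", "year", "value")
  stopifnot(all(need %in% names(abundance)))
  ids <- unique(abundance$population_id)
  pieces <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- abundance[abundance$population_id == ids[i], , drop = FALSE]
    s <- s[order(s$year), , drop = FALSE]
    span <- max(s$year) - min(s$year) + 1L
    v <- tryCatch(log_abundance(s$value, config$zero_replace_frac),
                  error = function(e) NULL)
    if (nrow(s) < 2L || span < config$min_span || is.null(v)) {
      pieces[[i]] <- data.frame(series_id = ids[i], year = s$year[1L],
                                value = NA_real_, ok = FALSE,
                                reason = if (is.null(v)) "all_zero" else "too_short",
                                stringsAsFactors = FALSE)
    } else {
      pieces[[i]] <- data.frame(series_id = ids[i], year = s$year, value = v,
                                ok = TRUE, reason = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, pieces)
  good <- long[long$ok, c("series_id", "year", "value")]
  bt <- batch_trends(good, window, config)
  bad <- unique(long[!long$ok, c("series_id", "reason")])
  if (nrow(bad)) {
    extra <- data.frame(series_id = bad$series_id, method = NA_character_,
                        n_obs = NA_integer_, r_squared = NA_real_,
                        mean_trend = NA_real_, retained = FALSE,
                        rejection_reason = bad$reason, stringsAsFactors = FALSE)
    bt$trends <- rbind(bt$trends, extra)
  }
  meta <- unique(abundance[, c("population_id", "binomial", "order_name",
                               "region", "country", "taxon_class")])
  out <- merge(bt$trends, meta, by.x = "series_id", by.y = "population_id",
               all.x = TRUE, sort = FALSE)
  names(out)[names(out) == "series_id"] <- "population_id"
  out <- out[order(out$population_id), , drop = FALSE]
  rownames(out) <- NULL
  list(trends = out, fits = bt$fits)
}

#' SDG indicator trends
#'
#' Runs the trend chain over a long country-by-indicator table. Each
#' indicator's cross-country minimum determines the positive-shift centering,
#' and `log_required` indicators are log10-transformed, before fitting one
#' trend per (country, indicator) series.
#'
#' @param indicators Data frame with columns `country`, `indicator_code`,
#'   `year`, `value`.
#' @param indicator_meta Data frame with columns `indicator_code`,
#'   `log_required`, `invert`.
#' @param window A [study_window()].
#' @param config A [trend_config()].
#' @return A list with `trends` (columns `country`, `indicator_code` plus the
#'   batch-table columns) and `fits`.
#' @export
indicator_trends <- function(indicators, indicator_meta,
                             window = study_window(),
                             config = trend_config()) {
  stopifnot(all(c("country", "indicator_code", "year", "value") %in%
                  names(indicators)))
  stopifnot(all(c("indicator_code", "log_required") %in% names(indicator_meta)))
  cmin <- tapply(indicators$value, indicators$indicator_code, min)
  logreq <- stats::setNames(as.logical(indicator_meta$log_required),
                            indicator_meta$indicator_code)
  sep <- "\r"  # never occurs in country or indicator codes
  tf <- indicators
  # transform per indicator with the shared cross-country minimum
  for (code in unique(indicators$indicator_code)) {
    sel <- indicators$indicator_code == code
    tf$value[sel] <- transform_indicator(indicators$value[sel],
                                         log_required = isTRUE(logreq[[code]]),
                                         cross_min = cmin[[code]],
                                         shift_eps = config$shift_eps)
  }
  tf$series_id <- paste(tf$country, tf$indicator_code, sep = sep)
  bt <- batch_trends(tf[, c("series_id", "year", "value")], window, config)
  parts <- strsplit(bt$trends$series_id, sep, fixed = TRUE)
  bt$trends$country <- vapply(parts, `[`, "", 1L)
  bt$trends$indicator_code <- vapply(parts, `[`, "", 2L)
  bt$trends$series_id <- NULL
  bt$trends <- bt$trends[order(bt$trends$indicator_code, bt$trends$country),
                         c("country", "indicator_code", "method", "n_obs",
                           "r_squared", "mean_trend", "retained",
                           "rejection_reason")]
  rownames(bt$trends) <- NULL
  bt
}
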