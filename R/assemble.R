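#' Three-step homogenization of a country-by-indicator panel
#'
#' Prunes a sparse availability table into a complete block, in a fixed
#' order: (1) remove data-poor countries holding fewer than
#' `ceil(min_indicator_fraction * n_indicators)` indicators; (2) remove
#' data-poor indicators whose associated wildlife-population total over the
#' remaining countries falls below `min_populations`; (3) remove any
#' remaining country that lacks one of the retained indicators, so the
#' result has no gaps. With the default fraction 0.5 and 42 indicators,
#' step 1 is the "fewer than 21 indicators" cut.
#'
#' A step-3 removal can push an indicator's population total back below the
#' step-2 threshold, so one pass over the steps is not in general a closure
#' operation. The three steps are therefore repeated, in the same fixed
#' order, until nothing changes (`iterate = TRUE`, the default), making the
#' result a true fixed point: homogenizing the output changes nothing. On
#' panels where a single pass is already self-consistent — the typical case —
#' the two behaviors coincide; `iterate = FALSE` gives the literal single
#' pass.
#'
#' @param availability Logical matrix, countries in rows, indicators in
#'   columns (dimnames required): `TRUE` where a retained indicator trend
#'   exists for that country.
#' @param pop_counts Named vector of retained wildlife-population counts per
#'   country (names must cover the rows of `availability`).
#' @param min_indicator_fraction Fraction of the current indicator set a
#'   country must hold to survive step 1 (default 0.5).
#' @param min_populations Minimum wildlife-population total associated with
#'   an indicator (default 160).
#' @param complete_cases Whether to apply step 3 (default `TRUE`).
#' @param iterate Repeat the three steps to a fixed point (default `TRUE`).
#' @return A list of class `homogenization` with `countries` and `indicators`
#'   (retained, in input order) and `audit` (one row per removal: `pass`,
#'   `step`, `entity_type`, `entity`, `reason`).
#' @export
homogenize_panel <- function(availability, pop_counts,
                             min_indicator_fraction = 0.5,
                             min_populations = 160L,
                             complete_cases = TRUE,
                             iterate = TRUE) {
  stopifnot(is.matrix(availability), is.logical(availability),
            !is.null(rownames(availability)), !is.null(colnames(availability)))
  stopifnot(min_indicator_fraction > 0, min_indicator_fraction <= 1,
            min_populations >= 1)
  countries <- rownames(availability)
  indicators <- colnames(availability)
  if (!all(countries %in% names(pop_counts)))
    stop("pop_counts must be named for every country in the availability table")
  pop_counts <- pop_counts[countries]
  audit <- list()
  log_removal <- function(pass, step, type, entity, reason) {
    audit[[length(audit) + 1L]] <<- data.frame(
      pass = pass, step = step, entity_type = type, entity = entity,
      reason = reason, stringsAsFactors = FALSE)
  }

  pass <- 0L
  repeat {
    pass <- pass + 1L
    before <- c(countries, "/", indicators)

    # step 1: data-poor countries
    need <- ceiling(min_indicator_fraction * length(indicators))
    sub <- availability[countries, indicators, drop = FALSE]
    have <- rowSums(sub)
    for (ct in countries[have < need])
      log_removal(pass, 1L, "country", ct,
                  sprintf("has %d of %d indicators (minimum %d)",
                          have[[ct]], length(indicators), need))
    countries <- countries[have >= need]
    if (!length(countries))
      stop("homogenization emptied panel: step 1 (country indicator-count cut) removed all countries")

    # step 2: data-poor indicators, by associated population totals
    sub <- availability[countries, indicators, drop = FALSE]
    assoc <- colSums(sub * pop_counts[countries])
    for (ic in indicators[assoc < min_populations])
      log_removal(pass, 2L, "indicator", ic,
                  sprintf("associated with %g wildlife populations (minimum %d)",
                          assoc[[ic]], min_populations))
    indicators <- indicators[assoc >= min_populations]
    if (!length(indicators))
      stop("homogenization emptied panel: step 2 (indicator population cut) removed all indicators")

    # step 3: countries with incomplete data over the retained indicators
    if (complete_cases) {
      sub <- availability[countries, indicators, drop = FALSE]
      incomplete <- rowSums(sub) < length(indicators)
      for (ct in countries[incomplete])
        log_removal(pass, 3L, "country", ct,
                    sprintf("missing retained indicator(s): %s",
                            paste(indicators[!sub[ct, ]], collapse = ", ")))
      countries <- countries[!incomplete]
      if (!length(countries))
        stop("homogenization emptied panel: step 3 (complete-case cut) removed all countries")
    }

    if (!iterate || identical(before, c(countries, "/", indicators))) break
  }

  audit <- if (length(audit)) do.call(rbind, audit)
  else data.frame(pass = integer(), step = integer(),
                  entity_type = character(), entity = character(),
                  reason = character(), stringsAsFactors = FALSE)
  structure(list(countries = countries, indicators = indicators,
                 audit = audit),
            class = "homogenization")
}

#' @export
print.homogenization <- function(x, ...) {
  cat(sprintf("homogenized panel: %d countries x %d indicators (%d removals)\n",
              length(x$countries), length(x$indicators), nrow(x$audit)))
  invisible(x)
}

#' Orient and z-score indicator trends across countries
#'
#' Applies the orientation convention (indicators whose raw direction runs
#' against desirable progress are multiplied by -1) and then z-scores each
#' indicator's trend across countries, so a regression coefficient is
#' expressed per 1 SD of oriented indicator trend. Orientation precedes
#' normalization, so flipping the invert flag exactly negates the z-scores.
#'
#' @param trends Data frame with columns `country`, `indicator_code`,
#'   `mean_trend`.
#' @param invert Named logical vector (by indicator code); codes absent from
#'   it are not inverted.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A list with `z` (country, indicator_code, z) and `excluded`
#'   (indicator_code, reason) for indicators with undefined cross-country SD.
#' @export
zscore_orient <- function(trends, invert = logical(),
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("country", "indicator_code", "mean_trend") %in% names(trends)))
  out <- list(); excl <- list()
  for (code in unique(trends$indicator_code)) {
    s <- trends[trends$indicator_code == code, , drop = FALSE]
    x <- s$mean_trend * if (isTRUE(unname(invert[code]))) -1 else 1
    n <- length(x)
    sdx <- stats::sd(x)
    if (sd_type == "population") sdx <- sdx * sqrt((n - 1) / n)
    if (n < 2L || !is.finite(sdx) || sdx == 0) {
      excl[[length(excl) + 1L]] <- data.frame(
        indicator_code = code,
        reason = if (n < 2L) "fewer than 2 countries" else "zero cross-country SD",
        stringsAsFactors = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      country = s$country, indicator_code = code,
      z = (x - mean(x)) / sdx, stringsAsFactors = FALSE)
  }
  list(z = if (length(out)) do.call(rbind, out)
       else data.frame(country = character(), indicator_code = character(),
                       z = numeric(), stringsAsFactors = FALSE),
       excluded = if (length(excl)) do.call(rbind, excl)
       else data.frame(indicator_code = character(), reason = character(),
                       stringsAsFactors = FALSE))
}

#' Assemble modelling records
#'
#' Cross-joins each retained wildlife trend with every retained indicator
#' z-score of its country and attaches the log10-transformed country
#' covariates (land area, 1996 human population density). Birds and mammals
#' are kept distinguishable through `taxon_class` and modelled separately
#' downstream. Populations in countries outside the homogenized set are
#' dropped with an audit entry.
#'
#' @param wildlife Data frame of retained wildlife trends with columns
#'   `population_id`, `binomial`, `order_name`, `region`, `country`,
#'   `taxon_class`, `mean_trend`.
#' @param indicator_z The `z` table from [zscore_orient()].
#' @param country_meta Data frame with `country`, `land_area_km2`, `hpd_1996`.
#' @return A list with `rows` (one modelling record per population x
#'   indicator: `population_id`, `species`, `order`, `region`, `country`,
#'   `taxon_class`, `response`, `indicator_code`, `x`, `log_land_area`,
#'   `log_hpd_1996`) and `dropped` (population_id, reason).
#' @export
assemble_model_rows <- function(wildlife, indicator_z, country_meta) {
  need <- c("population_id", "binomial", "order_name", "region", "country",
            "taxon_class", "mean_trend")
  stopifnot(all(need %in% names(wildlife)))
  countries <- unique(indicator_z$country)
  if (!all(countries %in% country_meta$country))
    stop("country metadata missing for: ",
         paste(setdiff(countries, country_meta$country), collapse = ", "))
  inside <- wildlife$country %in% countries
  dropped <- if (any(!inside)) data.frame(
    population_id = wildlife$population_id[!inside],
    reason = sprintf("country %s not in homogenized set",
                     wildlife$country[!inside]),
    stringsAsFactors = FALSE)
  else data.frame(population_id = character(), reason = character(),
                  stringsAsFactors = FALSE)
  w <- wildlife[inside, , drop = FALSE]
  rows <- merge(w, indicator_z, by = "country")
  cm <- country_meta[, c("country", "land_area_km2", "hpd_1996")]
  rows <- merge(rows, cm, by = "country")
  out <- data.frame(population_id = rows$population_id,
                    species = rows$binomial,
                    order = rows$order_name,
                    region = rows$region,
                    country = rows$country,
                    taxon_class = rows$taxon_class,
                    response = rows$mean_trend,
                    indicator_code = rows$indicator_code,
                    x = rows$z,
                    log_land_area = log10(rows$land_area_km2),
                    log_hpd_1996 = log10(rows$hpd_1996),
                    stringsAsFactors = FALSE)
  out <- out[order(out$taxon_class, out$indicator_code, out$population_id), ]
  rownames(out) <- NULL
  if (anyNA(out)) stop("assembled rows contain missing values")
  list(rows = out, dropped = dropped)
}

#' Pairwise Pearson correlations among indicator trends
#'
#' Pairwise-complete Pearson product-moment correlations between indicators'
#' (oriented, z-scored) cross-country trends, with two-sided t-test p-values.
#' Pairs observed in fewer than `min_n` common countries are reported as
#' undefined.
#'
#' @param indicator_z The `z` table from [zscore_orient()] (or any long table
#'   with `country`, `indicator_code` and a value column named `z`).
#' @param min_n Minimum common sample size per pair (default 3).
#' @return A data frame with one row per ordered pair (`ind_a`, `ind_b`,
#'   `r`, `n`, `p`); symmetric, with `r = 1` on the diagonal.
#' @export
indicator_correlations <- function(indicator_z, min_n = 3L) {
  codes <- sort(unique(indicator_z$indicator_code))
  wide <- stats::reshape(indicator_z[, c("country", "indicator_code", "z")],
                         idvar = "country", timevar = "indicator_code",
                         direction = "wide")
  m <- as.matrix(wide[, paste0("z.", codes), drop = FALSE])
  colnames(m) <- codes
  out <- expand.grid(ind_a = codes, ind_b = codes, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$n <- NA_integer_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    a <- m[, out$ind_a[i]]; b <- m[, out$ind_b[i]]
    ok <- stats::complete.cases(a, b)
    out$n[i] <- sum(ok)
    if (out$ind_a[i] == out$ind_b[i]) {
      out$r[i] <- 1; out$p[i] <- 0
    } else if (sum(ok) >= min_n && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      ct <- stats::cor.test(a[ok], b[ok])
      out$r[i] <- unname(ct$estimate); out$p[i] <- ct$p.value
    }
  }
  out
}
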