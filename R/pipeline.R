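#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> trend chain -> homogenize -> orient /
#' z-score -> assemble -> hierarchical fits -> reports, recording per-stage
#' counts in a manifest. Any stage error aborts with the manifest up to that
#' stage attached to the condition.
#'
#' @param cfg A [synth_config()]; used to generate data when `data` is NULL
#'   and to set the study window and the seed.
#' @param data Optional pre-built input list with components `abundance`,
#'   `indicators`, `indicator_meta`, `country_meta` and optionally `truth`
#'   (the [simulate_panel()] schema); bypasses simulation.
#' @param out_dir Optional directory; when given, all stage outputs and
#'   `manifest.json` are written there as plain-text CSV/JSON.
#' @param trend_cfg A [trend_config()].
#' @param min_indicator_fraction,min_populations,complete_cases
#'   Homogenization parameters (see [homogenize_panel()]). The default
#'   `min_populations` here is sized for synthetic panels; pass 160 for
#'   full-scale panels.
#' @param chains,iter,burnin,thin,ci_level,rhat_max Model settings (see
#'   [fit_indicator_models()]).
#' @return A list of class `devwild_run`: `manifest`, `panel`,
#'   `wildlife_trends`, `indicator_trends`, `homog`, `indicator_z`,
#'   `assembled`, `posteriors`, `correlations`, `recovery` (when truth is
#'   available) and `forest`.
#' @export
run_pipeline <- function(cfg = synth_config(), data = NULL, out_dir = NULL,
                         trend_cfg = trend_config(),
                         min_indicator_fraction = 0.5,
                         min_populations = 30L,
                         complete_cases = TRUE,
                         chains = 2L, iter = 2000L, burnin = 500L, thin = 1L,
                         ci_level = 0.95, rhat_max = 1.05) {
  window <- study_window(cfg$study_start, cfg$study_end)
  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), c("mask", "beta_true"))],
                   beta_true = as.list(cfg$beta_true),
                   seed = cfg$seed,
                   version = as.character(utils::packageVersion("devwild")),
                   counts = list())

  panel <- if (is.null(data)) simulate_panel(cfg) else data
  manifest$counts$populations_in <- length(unique(panel$abundance$population_id))
  manifest$counts$indicator_series_in <-
    nrow(unique(panel$indicators[, c("country", "indicator_code")]))

  wt <- wildlife_trends(panel$abundance, window, trend_cfg)
  wkeep <- wt$trends[wt$trends$retained, , drop = FALSE]
  manifest$counts$wildlife_trends_retained <- nrow(wkeep)
  if (nrow(wkeep) == 0L)
    stop("pipeline halted: no wildlife trends retained (check noise levels and retention thresholds)")

  it <- indicator_trends(panel$indicators, panel$indicator_meta, window,
                         trend_cfg)
  ikeep <- it$trends[it$trends$retained, , drop = FALSE]
  manifest$counts$indicator_trends_retained <- nrow(ikeep)
  if (nrow(ikeep) == 0L)
    stop("pipeline halted: no indicator trends retained")

  countries <- sort(unique(c(wkeep$country, ikeep$country)))
  codes <- sort(unique(panel$indicator_meta$indicator_code))
  avail <- matrix(FALSE, length(countries), length(codes),
                  dimnames = list(countries, codes))
  avail[cbind(ikeep$country, ikeep$indicator_code)] <- TRUE
  pop_counts <- table(factor(wkeep$country, levels = countries))
  pop_counts <- stats::setNames(as.numeric(pop_counts), countries)
  homog <- homogenize_panel(avail, pop_counts,
                            min_indicator_fraction = min_indicator_fraction,
                            min_populations = min_populations,
                            complete_cases = complete_cases)
  manifest$counts$countries_retained <- length(homog$countries)
  manifest$counts$indicators_retained <- length(homog$indicators)

  invert <- stats::setNames(as.logical(panel$indicator_meta$invert),
                            panel$indicator_meta$indicator_code)
  isub <- ikeep[ikeep$country %in% homog$countries &
                  ikeep$indicator_code %in% homog$indicators, , drop = FALSE]
  zo <- zscore_orient(isub, invert, sd_type = trend_cfg$sd_type)
  correlations <- if (length(unique(zo$z$indicator_code)) >= 2L)
    indicator_correlations(zo$z) else NULL

  asm <- assemble_model_rows(wkeep, zo$z, panel$country_meta)
  manifest$counts$rows_assembled <- nrow(asm$rows)
  manifest$counts$populations_dropped_at_assembly <- nrow(asm$dropped)
  if (nrow(asm$rows) == 0L)
    stop("pipeline halted: assembly produced no modelling rows")

  posteriors <- fit_indicator_models(asm$rows, chains = chains, iter = iter,
                                     burnin = burnin, thin = thin,
                                     ci_level = ci_level, rhat_max = rhat_max,
                                     seed = cfg$seed)
  manifest$counts$fits <- nrow(posteriors)
  manifest$counts$fits_converged <- sum(posteriors$converged)
  manifest$counts$fits_supported <- sum(posteriors$support)

  recovery <- if (!is.null(panel$truth))
    recovery_report(posteriors, panel$truth) else NULL
  forest <- forest_table(posteriors, invert)

  run <- structure(list(manifest = manifest, panel = panel,
                        wildlife_trends = wt$trends,
                        indicator_trends = it$trends,
                        homog = homog, indicator_z = zo$z,
                        assembled = asm$rows, posteriors = posteriors,
                        correlations = correlations,
                        recovery = recovery, forest = forest),
                   class = "devwild_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.devwild_run <- function(x, ...) {
  ct <- x$manifest$counts
  cat("devwild pipeline run\n")
  cat(sprintf("  trends retained for %d populations, in %d countries, with %d indicators\n",
              ct$wildlife_trends_retained, ct$countries_retained,
              ct$indicators_retained))
  cat(sprintf("  %d modelling rows; %d fits (%d converged, %d supported)\n",
              ct$rows_assembled, ct$fits, ct$fits_converged, ct$fits_supported))
  if (!is.null(x$recovery))
    cat(sprintf("  recovery: coverage %.2f, sign accuracy %s\n",
                x$recovery$coverage,
                ifelse(is.na(x$recovery$sign_accuracy), "NA",
                       sprintf("%.2f", x$recovery$sign_accuracy))))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes every stage table as CSV plus `manifest.json`; deterministic byte
#' content under a fixed configuration and seed.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "devwild_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                            row.names = FALSE)
  wr(run$wildlife_trends, "trends_wildlife.csv")
  wr(run$indicator_trends, "trends_indicators.csv")
  wr(run$homog$audit, "homogenization_audit.csv")
  wr(run$indicator_z, "indicator_z.csv")
  wr(run$assembled, "assembled.csv")
  for (tx in unique(run$assembled$taxon_class))
    wr(run$assembled[run$assembled$taxon_class == tx, ],
       sprintf("assembled_%ss.csv", tx))
  pt <- as.data.frame(run$posteriors)
  wr(pt, "posteriors.csv")
  for (tx in unique(pt$taxon_class))
    wr(pt[pt$taxon_class == tx, ], sprintf("posteriors_%ss.csv", tx))
  if (!is.null(run$correlations)) wr(run$correlations, "correlations.csv")
  if (!is.null(run$recovery)) wr(run$recovery$table, "recovery.csv")
  wr(run$forest, "forest.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare fitted posteriors against synthetic ground truth
#'
#' For each fitted indicator with a known planted effect: whether the
#' credible interval covers the truth and whether the posterior-mean sign
#' matches the planted sign (sign agreement is undefined for planted-zero
#' indicators and excluded from the aggregate). Indicators fitted but absent
#' from the truth are listed and excluded from aggregates.
#'
#' @param posteriors A [fit_indicator_models()] table.
#' @param truth The `truth` component of a [simulate_panel()] panel (or a
#'   list with element `beta_true`).
#' @return A list of class `recovery_report`: `table` (per fit: beta_true,
#'   beta_mean, CI, covered, sign_correct), `coverage`, `sign_accuracy`,
#'   `missing`.
#' @export
recovery_report <- function(posteriors, truth) {
  bt <- unlist(truth$beta_true)
  tab <- as.data.frame(posteriors)[, c("taxon_class", "indicator_code",
                                       "beta_mean", "ci_low", "ci_high",
                                       "support", "converged")]
  missing <- setdiff(unique(tab$indicator_code), names(bt))
  tab <- tab[tab$indicator_code %in% names(bt), , drop = FALSE]
  tab$beta_true <- unname(bt[tab$indicator_code])
  tab$covered <- tab$ci_low <= tab$beta_true & tab$beta_true <= tab$ci_high
  tab$sign_correct <- ifelse(tab$beta_true == 0, NA,
                             sign(tab$beta_mean) == sign(tab$beta_true))
  ok <- !is.na(tab$covered)
  structure(list(table = tab,
                 coverage = if (any(ok)) mean(tab$covered[ok]) else NA_real_,
                 sign_accuracy = if (any(!is.na(tab$sign_correct)))
                   mean(tab$sign_correct, na.rm = TRUE) else NA_real_,
                 missing = missing),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: CI coverage %.3f, sign accuracy %s over %d fits\n",
              x$coverage,
              ifelse(is.na(x$sign_accuracy), "NA",
                     sprintf("%.3f", x$sign_accuracy)), nrow(x$table)))
  if (length(x$missing))
    cat("fitted but absent from truth:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Ordered effect table (forest-plot data)
#'
#' One row per fitted indicator and taxon class with the proportional-change
#' point estimate and credible interval (per-draw `10^beta - 1`, i.e. the
#' proportional change in abundance trend per 1 SD of oriented indicator
#' trend), a support flag, and an asterisk appended to inverted indicators'
#' labels to mark the orientation flip.
#'
#' @param posteriors A [fit_indicator_models()] table.
#' @param invert Named logical vector of inversion flags by indicator code.
#' @return A data frame ordered by indicator code.
#' @export
forest_table <- function(posteriors, invert = logical()) {
  pt <- as.data.frame(posteriors)
  inv <- vapply(pt$indicator_code,
                function(code) isTRUE(unname(invert[code])), TRUE)
  out <- data.frame(taxon_class = pt$taxon_class,
                    indicator_code = pt$indicator_code,
                    label = paste0(pt$indicator_code, ifelse(inv, "*", "")),
                    inverted = inv,
                    prop_change = pt$prop_change,
                    prop_low = pt$prop_low, prop_high = pt$prop_high,
                    support = pt$support, converged = pt$converged,
                    stringsAsFactors = FALSE)
  out <- out[order(out$taxon_class, out$indicator_code), ]
  rownames(out) <- NULL
  out
}
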