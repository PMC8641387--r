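# Independent brute-force enumeration of the three homogenization steps
# (repeated to a fixed point), written against the rule text rather than
# sharing code with the package.
brute_homogenize <- function(avail, pops, frac = 0.5, minpop = 1) {
  cts <- rownames(avail); inds <- colnames(avail)
  repeat {
    prev <- list(cts, inds)
    need <- ceiling(frac * length(inds))
    keep_ct <- character()
    for (ct in cts) {
      cnt <- 0L
      for (ic in inds) if (avail[ct, ic]) cnt <- cnt + 1L
      if (cnt >= need) keep_ct <- c(keep_ct, ct)
    }
    if (!length(keep_ct)) return(NULL)
    keep_ic <- character()
    for (ic in inds) {
      tot <- 0
      for (ct in keep_ct) if (avail[ct, ic]) tot <- tot + pops[[ct]]
      if (tot >= minpop) keep_ic <- c(keep_ic, ic)
    }
    if (!length(keep_ic)) return(NULL)
    final_ct <- character()
    for (ct in keep_ct) {
      if (all(vapply(keep_ic, function(ic) avail[ct, ic], TRUE)))
        final_ct <- c(final_ct, ct)
    }
    if (!length(final_ct)) return(NULL)
    cts <- final_ct; inds <- keep_ic
    if (identical(list(cts, inds), prev)) return(list(countries = cts,
                                                      indicators = inds))
  }
}

# noiseless log-linear abundance series on the raw (exponentiated) scale
line_series <- function(years, slope, intercept = 2) 10^(intercept + slope * (years - years[1]))

# long-format series table for batch_trends
as_series <- function(id, years, values) {
  data.frame(series_id = id, year = years, value = values,
             stringsAsFactors = FALSE)
}
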