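#' Bayesian hierarchical linear model via conjugate Gibbs sampling
#'
#' Fits the Gaussian linear mixed model
#' \deqn{y_i = x_i'\beta + u_{s(i)} + u_{o(i)} + u_{r(i)} + \varepsilon_i}
#' with independent random intercepts for each grouping factor
#' (\eqn{u_g \sim N(0, \sigma_g^2)}), residual \eqn{\varepsilon_i \sim
#' N(0, \sigma^2)}, a vague normal prior \eqn{\beta_j \sim N(0,
#' \sigma^2_\beta)} on every fixed effect (default variance 1000, intercept
#' included) and Gamma(shape, rate) priors on each precision. The model is
#' linear-Gaussian throughout, so every full conditional is available in
#' closed form and the sampler is an exact-model Gibbs sampler: single-site
#' conjugate normal updates for each fixed effect, blocked normal updates for
#' each random-intercept vector, and gamma updates for the precisions.
#'
#' Non-intercept design columns are mean-centered internally by default
#' (improving mixing of the single-site updates); reported coefficients are
#' on the original scale except the intercept, which refers to
#' covariate-mean conditions.
#'
#' Grouping factors with fewer than 2 observed levels are dropped from the
#' model (recorded in `$dropped_factors`).
#'
#' @param formula Fixed-effects formula, e.g.
#'   `response ~ x + log_land_area + log_hpd_1996`.
#' @param data Data frame; must contain the model variables and the grouping
#'   factors.
#' @param random One-sided formula naming the grouping factors, e.g.
#'   `~ species + order + region`, or `NULL` for none.
#' @param fixed_prior_var Prior variance of each fixed effect (default 1000).
#' @param prec_prior Length-2 vector `c(shape, rate)` of the gamma prior on
#'   the residual and random-effect precisions (default `c(1, 5e-5)`).
#' @param chains,iter,burnin,thin MCMC settings (defaults 4 chains of 5000
#'   iterations, 1000 burn-in, no thinning).
#' @param seed Integer seed; chain seeds derive deterministically from it.
#' @param fix_sigma2 Optionally fix the residual variance at a known value
#'   (the residual precision is then not sampled).
#' @param center Mean-center non-intercept design columns (default `TRUE`).
#' @param keep_ranef Store random-intercept draws (needed for
#'   draw-exact [simulate.bhlm()]; posterior means are always stored).
#' @return An object of class `bhlm` with posterior draws (`$draws$beta`,
#'   `$draws$sigma2`, `$draws$sigma2_ranef`, per chain), posterior-mean random
#'   intercepts, diagnostics via [summary.bhlm()], and the usual accessors
#'   (`coef`, `predict`, `residuals`, `simulate`, `plot`).
#' @examples
#' d <- data.frame(x = rnorm(50), g = gl(5, 10))
#' d$y <- 0.5 * d$x + rnorm(50)
#' fit <- bhlm(y ~ x, d, random = ~ g, chains = 2, iter = 500, burnin = 100,
#'             seed = 1)
#' coef(fit)
#' @export
bhlm <- function(formula, data, random = NULL,
                 fixed_prior_var = 1000,
                 prec_prior = c(shape = 1, rate = 5e-5),
                 chains = 4L, iter = 5000L, burnin = 1000L, thin = 1L,
                 seed = 1L, fix_sigma2 = NULL, center = TRUE,
                 keep_ranef = FALSE) {
  stopifnot(fixed_prior_var > 0, length(prec_prior) == 2L, all(prec_prior > 0),
            chains >= 1L, iter > burnin, burnin >= 0L, thin >= 1L)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite values in response or design")

  col_means <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (center) {
    notint <- colnames(X) != "(Intercept)"
    col_means[notint] <- colMeans(X[, notint, drop = FALSE])
    X <- sweep(X, 2L, col_means)
  }

  groups <- list(); dropped <- character()
  if (!is.null(random)) {
    for (v in all.vars(random)) {
      f <- factor(data[[v]])
      if (nlevels(f) < 2L) {
        dropped <- c(dropped, v)
      } else {
        groups[[v]] <- f
      }
    }
  }

  p <- ncol(X)
  xtx <- colSums(X^2)
  gidx <- lapply(groups, as.integer)
  glev <- lapply(groups, nlevels)
  gcnt <- lapply(groups, function(f) tabulate(as.integer(f), nlevels(f)))
  a0 <- prec_prior[[1]]; b0 <- prec_prior[[2]]
  # orientation-equivariant noise: each fixed effect's standard-normal
  # deviate is multiplied by the (fixed) sign of its column's inner product
  # with y. A symmetric deviate times a constant sign is still N(0,1), and
  # the sampler becomes pathwise equivariant to sign flips of any design
  # column: flipping a column exactly negates that coefficient's draws and
  # leaves every other draw bit-identical under the same seed.
  jsgn <- ifelse(colSums(X * y) >= 0, 1, -1)
  # fixed-effect columns that are constant within a grouping's levels are
  # confounded with that grouping's intercepts (likelihood-flat direction);
  # record the group-level covariate values to enable translation moves
  gconst <- lapply(seq_along(groups), function(g) {
    idx <- gidx[[g]]
    out <- list()
    for (j in seq_len(p)) {
      lev_vals <- rowsum(X[, j], idx, reorder = TRUE) / gcnt[[g]]
      if (max(abs(X[, j] - lev_vals[idx])) < 1e-12)
        out[[as.character(j)]] <- as.numeric(lev_vals)
    }
    out
  })

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  n_keep <- length(seq.int(burnin + 1L, iter, by = thin))

  run_chain <- function(cs) {
    set.seed(cs)
    beta <- rep(0, p)
    u <- lapply(glev, function(L) rep(0, L))
    tau_e <- if (is.null(fix_sigma2)) 1 / max(stats::var(y), 1e-8)
             else 1 / fix_sigma2
    tau_g <- lapply(glev, function(L) 1)
    resid <- y - as.numeric(X %*% beta)

    B <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
    S2 <- numeric(n_keep)
    S2g <- matrix(NA_real_, n_keep, length(groups),
                  dimnames = list(NULL, names(groups)))
    Umean <- lapply(glev, function(L) rep(0, L))
    Udraws <- if (keep_ranef) lapply(glev, function(L) matrix(NA_real_, n_keep, L))
              else NULL
    k <- 0L
    for (it in seq_len(iter)) {
      # fixed effects: single-site conjugate normal updates
      for (j in seq_len(p)) {
        rj <- resid + X[, j] * beta[j]
        prec <- tau_e * xtx[j] + 1 / fixed_prior_var
        m <- tau_e * sum(X[, j] * rj) / prec
        beta[j] <- m + sqrt(1 / prec) * jsgn[j] * stats::rnorm(1L)
        resid <- rj - X[, j] * beta[j]
      }
      # random intercepts: blocked normal updates per factor
      for (g in seq_along(groups)) {
        idx <- gidx[[g]]
        rg <- resid + u[[g]][idx]
        s <- as.numeric(rowsum(rg, idx, reorder = TRUE))
        prec <- tau_e * gcnt[[g]] + tau_g[[g]]
        u[[g]] <- stats::rnorm(glev[[g]], tau_e * s / prec, sqrt(1 / prec))
        resid <- rg - u[[g]][idx]
        # translation moves: for each fixed effect constant within this
        # grouping's levels (intercept, group-level covariates), shift mass
        # between the coefficient and the intercept block along the
        # likelihood-flat direction (unit Jacobian; the residual, hence the
        # likelihood, is unchanged). The shift's full conditional comes from
        # the two Gaussian priors. This decorrelates group-level covariates
        # from the random intercepts, which single-site updates mix poorly.
        for (jc in names(gconst[[g]])) {
          j <- as.integer(jc)
          xg <- gconst[[g]][[jc]]
          P <- 1 / fixed_prior_var + tau_g[[g]] * sum(xg^2)
          md <- (-beta[j] / fixed_prior_var +
                   tau_g[[g]] * sum(xg * u[[g]])) / P
          delta <- md + sqrt(1 / P) * jsgn[j] * stats::rnorm(1L)
          beta[j] <- beta[j] + delta
          u[[g]] <- u[[g]] - delta * xg
        }
        tau_g[[g]] <- stats::rgamma(1L, a0 + glev[[g]] / 2,
                                    b0 + sum(u[[g]]^2) / 2)
      }
      # residual precision
      if (is.null(fix_sigma2))
        tau_e <- stats::rgamma(1L, a0 + n / 2, b0 + sum(resid^2) / 2)
      if (it > burnin && (it - burnin - 1L) %% thin == 0L) {
        k <- k + 1L
        B[k, ] <- beta
        S2[k] <- 1 / tau_e
        for (g in seq_along(groups)) {
          S2g[k, g] <- 1 / tau_g[[g]]
          Umean[[g]] <- Umean[[g]] + u[[g]]
          if (keep_ranef) Udraws[[g]][k, ] <- u[[g]]
        }
      }
    }
    if (!all(is.finite(B)) || !all(is.finite(S2)))
      stop("sampler diverged: non-finite posterior draws")
    list(beta = B, sigma2 = S2, sigma2_ranef = S2g,
         u_mean = lapply(Umean, function(x) x / max(k, 1L)),
         u_draws = Udraws)
  }

  res <- lapply(chain_seeds, run_chain)

  u_mean <- NULL
  if (length(groups)) {
    u_mean <- lapply(seq_along(groups), function(g) {
      v <- Reduce(`+`, lapply(res, function(r) r$u_mean[[g]])) / chains
      stats::setNames(v, levels(groups[[g]]))
    })
    names(u_mean) <- names(groups)
  }

  structure(list(
    call = match.call(),
    formula = formula, random = random,
    terms = stats::terms(mf),
    y = y, X = X, col_means = col_means, center = center,
    groups = groups, dropped_factors = dropped,
    prior = list(fixed_prior_var = fixed_prior_var, prec_prior = prec_prior,
                 fix_sigma2 = fix_sigma2),
    mcmc = list(chains = chains, iter = iter, burnin = burnin, thin = thin,
                seed = seed, n_keep = n_keep),
    draws = list(beta = lapply(res, `[[`, "beta"),
                 sigma2 = lapply(res, `[[`, "sigma2"),
                 sigma2_ranef = lapply(res, `[[`, "sigma2_ranef"),
                 u = if (keep_ranef) lapply(res, `[[`, "u_draws")),
    ranef_mean = u_mean), class = "bhlm")
}

# ---- convergence diagnostics (split-Rhat, effective sample size) ----

#' Split-Rhat potential scale reduction
#'
#' Each chain is split in half; Rhat compares between- and within-half
#' variances in the usual way. Values near 1 indicate convergence.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar Rhat (NA when fewer than 4 draws per chain or zero
#'   within-chain variance).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[seq.int(nrow(x) - n + 1L, nrow(x)), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2L, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(mu)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial monotone positive
#' sequence, pooled over chains.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_draws <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(x, 2L, stats::var))
  mu <- colMeans(x)
  var_plus <- (n - 1) / n * W + if (m > 1L) n * stats::var(mu) / n else 0
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  max_lag <- min(n - 2L, 500L)
  acov <- sapply(seq_len(m), function(j)
    stats::acf(x[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1L, 1L])
  acov <- rowMeans(acov)
  rho <- 1 - (W - acov[-1L]) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 1
  prev <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
    t <- t + 2L
  }
  m * n / max(tau, 1e-12)
}

.draw_matrix <- function(fit, what, col) {
  # iterations x chains matrix for one scalar parameter
  do.call(cbind, lapply(fit$draws[[what]], function(d) {
    if (is.matrix(d)) d[, col] else d
  }))
}

#' Summarize a vector of posterior draws
#'
#' Equal-tailed credible interval, posterior mean/SD and the support flag
#' (interval excludes zero) for a single scalar parameter.
#'
#' @param draws Numeric vector (or matrix, flattened) of at least 100 draws.
#' @param ci_level Credible level (default 0.95).
#' @return A one-row data frame: `mean`, `sd`, `ci_low`, `ci_high`,
#'   `support`.
#' @export
summarize_draws <- function(draws, ci_level = 0.95) {
  draws <- as.numeric(draws)
  stopifnot(ci_level > 0, ci_level < 1)
  if (length(draws) < 100L)
    stop("too few draws to summarize (need at least 100)")
  q <- .eq_tail_ci(draws, ci_level)
  data.frame(mean = mean(draws), sd = stats::sd(draws),
             ci_low = q[1L], ci_high = q[2L],
             support = q[1L] > 0 || q[2L] < 0)
}

# Equal-tailed interval whose upper bound is the negated lower quantile of
# the negated draws: mathematically identical to the usual type-7 upper
# quantile, but floating-point symmetric, so the interval of -x is exactly
# the negation of the interval of x (sign-flip equivariance of reports).
.eq_tail_ci <- function(x, level) {
  alpha <- (1 - level) / 2
  c(unname(stats::quantile(x, alpha)), -unname(stats::quantile(-x, alpha)))
}

#' Summarize posterior draws
#'
#' Posterior means, SDs, equal-tailed credible intervals, split-Rhat and
#' effective sample sizes for the fixed effects and variance components.
#' A fit whose maximum fixed-effect Rhat exceeds `rhat_max` is flagged
#' not-converged; support claims should be disregarded for such fits.
#'
#' @param object A [bhlm()] fit.
#' @param ci_level Credible level (default 0.95).
#' @param rhat_max Convergence flag threshold (default 1.05).
#' @param ... Unused.
#' @return A list of class `summary.bhlm` with `coefficients` (one row per
#'   fixed effect: mean, sd, ci_low, ci_high, support, rhat, ess),
#'   `variances` and `converged`.
#' @export
summary.bhlm <- function(object, ci_level = 0.95, rhat_max = 1.05, ...) {
  stopifnot(ci_level > 0, ci_level < 1)
  if (object$mcmc$n_keep * object$mcmc$chains < 100L)
    stop("too few post-burn-in draws to summarize (need at least 100)")
  alpha <- (1 - ci_level) / 2
  cn <- colnames(object$draws$beta[[1L]])
  coefs <- do.call(rbind, lapply(seq_along(cn), function(j) {
    m <- .draw_matrix(object, "beta", j)
    cbind(data.frame(term = cn[j], stringsAsFactors = FALSE),
          summarize_draws(m, ci_level),
          data.frame(rhat = split_rhat(m), ess = ess_draws(m)))
  }))
  rownames(coefs) <- NULL
  vnames <- c("sigma2_resid",
              if (length(object$groups)) paste0("sigma2_", names(object$groups)))
  vrows <- list()
  v <- as.numeric(.draw_matrix(object, "sigma2", 1L))
  vrows[[1L]] <- data.frame(component = "sigma2_resid", mean = mean(v),
                            sd = stats::sd(v),
                            ci_low = unname(stats::quantile(v, alpha)),
                            ci_high = unname(stats::quantile(v, 1 - alpha)),
                            stringsAsFactors = FALSE)
  for (g in seq_along(object$groups)) {
    m <- do.call(cbind, lapply(object$draws$sigma2_ranef, function(d) d[, g]))
    v <- as.numeric(m)
    vrows[[g + 1L]] <- data.frame(component = vnames[g + 1L], mean = mean(v),
                                  sd = stats::sd(v),
                                  ci_low = unname(stats::quantile(v, alpha)),
                                  ci_high = unname(stats::quantile(v, 1 - alpha)),
                                  stringsAsFactors = FALSE)
  }
  variances <- do.call(rbind, vrows)
  converged <- all(is.na(coefs$rhat) | coefs$rhat <= rhat_max)
  structure(list(coefficients = coefs, variances = variances,
                 converged = converged, ci_level = ci_level,
                 rhat_max = rhat_max,
                 dropped_factors = object$dropped_factors,
                 mcmc = object$mcmc),
            class = "summary.bhlm")
}

#' @export
print.summary.bhlm <- function(x, digits = 4, ...) {
  cat(sprintf("Bayesian hierarchical linear model (%d chains x %d draws%s)\n",
              x$mcmc$chains, x$mcmc$n_keep,
              if (x$converged) "" else "; NOT CONVERGED"))
  cat("\nFixed effects (posterior mean, ", 100 * x$ci_level,
      "% equal-tailed CI):\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat("\nVariance components:\n")
  print(format(x$variances, digits = digits), row.names = FALSE)
  if (length(x$dropped_factors))
    cat("\nDropped grouping factors (<2 levels):",
        paste(x$dropped_factors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.bhlm <- function(x, ...) {
  cat("Bayesian hierarchical linear model (conjugate Gibbs)\n")
  cat("  formula:", deparse(x$formula), "\n")
  if (length(x$groups))
    cat("  random intercepts:", paste(names(x$groups), collapse = " + "), "\n")
  cat(sprintf("  n = %d; %d chains x %d iterations (burn-in %d)\n",
              length(x$y), x$mcmc$chains, x$mcmc$iter, x$mcmc$burnin))
  cat("  posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.bhlm <- function(object, ...) {
  cn <- colnames(object$draws$beta[[1L]])
  stats::setNames(vapply(seq_along(cn), function(j)
    mean(.draw_matrix(object, "beta", j)), 0), cn)
}

#' @export
fitted.bhlm <- function(object, ...) {
  eta <- as.numeric(object$X %*% coef(object))
  for (g in names(object$groups))
    eta <- eta + object$ranef_mean[[g]][as.integer(object$groups[[g]])]
  unname(eta)
}

#' @export
residuals.bhlm <- function(object, ...) object$y - fitted(object)

#' Predict from a fitted hierarchical model
#'
#' Posterior-mean predictions. For `newdata`, random intercepts of unseen
#' group levels contribute 0 (their prior mean).
#'
#' @param object A [bhlm()] fit.
#' @param newdata Optional data frame.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.bhlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  X <- sweep(X, 2L, object$col_means[colnames(X)])
  eta <- as.numeric(X %*% coef(object)[colnames(X)])
  for (g in names(object$groups)) {
    if (g %in% names(newdata)) {
      u <- object$ranef_mean[[g]][as.character(newdata[[g]])]
      u[is.na(u)] <- 0
      eta <- eta + u
    }
  }
  unname(eta)
}

#' Simulate responses from the posterior
#'
#' Each simulation picks one posterior draw and generates a new response
#' vector. When random-effect draws were stored (`keep_ranef = TRUE`) the
#' realized intercepts of that draw are used; otherwise fresh intercepts are
#' drawn from their fitted distributions (posterior predictive for new
#' groups).
#'
#' @param object A [bhlm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.bhlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  beta_all <- do.call(rbind, object$draws$beta)
  s2_all <- unlist(object$draws$sigma2)
  s2g_all <- if (length(object$groups))
    do.call(rbind, object$draws$sigma2_ranef)
  n <- length(object$y)
  out <- matrix(NA_real_, n, nsim)
  idx <- sample.int(nrow(beta_all), nsim, replace = TRUE)
  for (s in seq_len(nsim)) {
    i <- idx[s]
    eta <- as.numeric(object$X %*% beta_all[i, ])
    for (g in seq_along(object$groups)) {
      f <- object$groups[[g]]
      if (!is.null(object$draws$u)) {
        ch <- (i - 1L) %/% object$mcmc$n_keep + 1L
        row <- i - (ch - 1L) * object$mcmc$n_keep
        u <- object$draws$u[[ch]][[g]][row, ]
      } else {
        u <- stats::rnorm(nlevels(f), 0, sqrt(s2g_all[i, g]))
      }
      eta <- eta + u[as.integer(f)]
    }
    out[, s] <- eta + stats::rnorm(n, 0, sqrt(s2_all[i]))
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Trace plots for a fitted hierarchical model
#'
#' @param x A [bhlm()] fit.
#' @param pars Fixed-effect names to plot (default all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.bhlm <- function(x, pars = NULL, ...) {
  cn <- colnames(x$draws$beta[[1L]])
  if (is.null(pars)) pars <- cn
  pars <- intersect(pars, cn)
  old <- graphics::par(mfrow = c(length(pars), 1L), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    m <- .draw_matrix(x, "beta", match(p, cn))
    graphics::matplot(m, type = "l", lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}
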