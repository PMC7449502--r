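#' Prior specification for the hierarchical model
#'
#' Coefficients get independent zero-mean normal priors with a stated
#' precision (the default 0.001 corresponds to sd ~ 31.6, effectively
#' uninformative on log/ilr scales). The residual and population-intercept
#' variances get Gamma(shape, rate) priors on their precisions
#' `1/sigma^2` and `1/sigma_pop^2` — the conventional conjugate formulation;
#' Gamma(0.001, 0.001) has mean 1 and variance 1000.
#'
#' @param coef_precision Prior precision of every fixed coefficient.
#' @param gamma_shape,gamma_rate Gamma hyperparameters for both precisions.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_precision = 0.001, gamma_shape = 0.001,
                       gamma_rate = 0.001) {
  stopifnot(coef_precision > 0, gamma_shape > 0, gamma_rate > 0)
  structure(list(coef_precision = coef_precision,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults follow the analysis protocol: three chains retaining at least
#' 10,000 valid draws each after burn-in and thinning. Tests and examples
#' pass smaller values explicitly.
#'
#' @param n_chains Number of chains (>= 2 so convergence can be diagnosed).
#' @param n_draws Retained draws per chain after burn-in/thinning.
#' @param burn_in Discarded initial iterations per chain.
#' @param thin Thinning interval.
#' @param seed Base RNG seed; chain c uses `seed + c - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_draws = 10000, burn_in = 1000,
                        thin = 1, seed = 1) {
  stopifnot(n_chains >= 2, n_draws >= 1, burn_in >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Gibbs sampler for the Gaussian random-intercept linear model
#'
#' Samples the posterior of `y = X beta + u[group] + e`,
#' `e ~ N(0, sigma^2)`, `u_j ~ N(0, sigma_pop^2)`, under the priors of
#' [prior_spec]. All full conditionals are conjugate, so the sampler is an
#' exact Gibbs scheme with no tuning: `(beta, u)` are drawn jointly from
#' their multivariate-normal full conditional (blocking removes the slow
#' mixing between the intercept and the mean of the random intercepts) and
#' the two precisions from gamma full conditionals. Draws are reproducible
#' bit-for-bit from the seed.
#'
#' @param X Design matrix (full column rank).
#' @param y Response vector.
#' @param group Factor mapping rows to populations.
#' @param prior A [prior_spec].
#' @param mcmc An [mcmc_config].
#' @return An object of class `leuko_draws`: list with `draws` (matrix, one
#'   row per retained draw; columns are the fixed coefficients, the
#'   population intercepts `u_<level>`, `sigma` and `sigma_pop`), `chain` and
#'   `iteration` index vectors, `parnames`, `group_levels` and the config.
#' @export
gibbs_lmm <- function(X, y, group, prior = prior_spec(), mcmc = mcmc_config()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  group <- droplevels(as.factor(group))
  n <- nrow(X); p <- ncol(X); J <- nlevels(group)
  if (length(y) != n || length(group) != n)
    stop("X, y and group must agree in length")
  gi <- as.integer(group)
  n_j <- tabulate(gi, J)

  XtX <- crossprod(X)
  XtZ <- t(rowsum(X, gi, reorder = TRUE))        # p x J
  Xty <- drop(crossprod(X, y))
  Zty <- drop(rowsum(y, gi, reorder = TRUE))
  q <- p + J
  tau0 <- prior$coef_precision
  a <- prior$gamma_shape; b <- prior$gamma_rate

  ls_fit <- stats::lm.fit(X, y)
  beta_hat <- ls_fit$coefficients
  s2_hat <- max(stats::var(ls_fit$residuals), 1e-8)

  parnames <- c(colnames(X), paste0("u_", levels(group)), "sigma", "sigma_pop")
  total <- mcmc$n_chains * mcmc$n_draws
  draws <- matrix(NA_real_, total, p + J + 2L,
                  dimnames = list(NULL, parnames))
  chain_ix <- integer(total); iter_ix <- integer(total)

  row0 <- 0L
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    # dispersed but reasonable starting values
    beta <- beta_hat + stats::rnorm(p, 0, sqrt(s2_hat) * 0.5)
    u <- stats::rnorm(J, 0, sqrt(s2_hat) * 0.5)
    sigma2 <- s2_hat * stats::runif(1, 0.5, 2)
    sig2pop <- s2_hat * stats::runif(1, 0.1, 1)

    n_iter <- mcmc$burn_in + mcmc$n_draws * mcmc$thin
    kept <- 0L
    prec <- matrix(0, q, q)
    bvec <- c(Xty, Zty)
    for (it in seq_len(n_iter)) {
      # joint (beta, u) block
      prec[1:p, 1:p] <- XtX / sigma2
      diag(prec)[1:p] <- diag(XtX) / sigma2 + tau0
      prec[1:p, (p + 1):q] <- XtZ / sigma2
      prec[(p + 1):q, 1:p] <- t(XtZ) / sigma2
      prec[(p + 1):q, (p + 1):q] <- 0
      diag(prec)[(p + 1):q] <- n_j / sigma2 + 1 / sig2pop
      R <- chol(prec)
      m <- backsolve(R, backsolve(R, bvec / sigma2, transpose = TRUE))
      theta <- drop(m + backsolve(R, stats::rnorm(q)))
      beta <- theta[1:p]
      u <- theta[(p + 1):q]
      # residual precision
      res <- y - drop(X %*% beta) - u[gi]
      sigma2 <- 1 / stats::rgamma(1, a + n / 2, b + sum(res^2) / 2)
      # population precision
      sig2pop <- 1 / stats::rgamma(1, a + J / 2, b + sum(u^2) / 2)

      if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
        kept <- kept + 1L
        draws[row0 + kept, ] <- c(beta, u, sqrt(sigma2), sqrt(sig2pop))
        chain_ix[row0 + kept] <- ch
        iter_ix[row0 + kept] <- kept
      }
    }
    row0 <- row0 + mcmc$n_draws
  }

  structure(list(draws = draws, chain = chain_ix, iteration = iter_ix,
                 parnames = parnames, n_fixed = p,
                 group_levels = levels(group),
                 prior = prior, mcmc = mcmc),
            class = "leuko_draws")
}

#' @export
print.leuko_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$draws), "retained (",
      x$mcmc$n_chains, "chains x", x$mcmc$n_draws, "draws );",
      length(x$parnames), "parameters\n")
  invisible(x)
}

#' @export
as.matrix.leuko_draws <- function(x, ...) x$draws

#' Fit the Bayesian cosinor random-intercept mixed model
#'
#' The central fitting function: builds the cosinor/sex/size/latitude design
#' for one hematological response (see [build_design]), runs the Gibbs
#' sampler of [gibbs_lmm] with population as a random intercept, attaches
#' convergence diagnostics, and returns a fitted-model object with the usual
#' accessor methods (`print`, `summary`, `coef`, `predict`, `simulate`,
#' `residuals`, `fitted`, `plot`).
#'
#' @inheritParams build_design
#' @param prior A [prior_spec].
#' @param mcmc An [mcmc_config].
#' @return An object of class `cosinor_lmm` containing the posterior draws
#'   (`$draws`, a [gibbs_lmm] result), design metadata (standardization
#'   centers/scales, ilr basis, period), the data used, and the convergence
#'   report.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(seed = 1)
#' fit <- cosinor_lmm(sim$cohort, "log_wbc",
#'                    mcmc = mcmc_config(n_draws = 500, burn_in = 200))
#' summary(fit)
#' }
#' @export
cosinor_lmm <- function(cohort, response = "log_wbc", period_days = 365,
                        basis = ilr_basis(5), delta = 0.65 / 150,
                        prior = prior_spec(), mcmc = mcmc_config(),
                        standardization = NULL) {
  des <- build_design(cohort, response, period_days, basis, delta,
                      standardization)
  draws <- gibbs_lmm(des$X, des$y, des$group, prior, mcmc)
  fit <- structure(
    list(draws = draws, design = des, response = response,
         response_kind = if (response == "log_wbc") "log" else "ilr",
         cohort = cohort, call = match.call()),
    class = "cosinor_lmm")
  fit$convergence <- check_convergence(draws)
  if (!fit$convergence$pass)
    warning("convergence diagnostics failed for response '", response,
            "'; inspect $convergence (worst R-hat ",
            signif(max(fit$convergence$report$rhat), 4), ")")
  fit
}

.fixed_draws <- function(fit) {
  fit$draws$draws[, seq_len(fit$draws$n_fixed), drop = FALSE]
}

#' @export
print.cosinor_lmm <- function(x, ...) {
  cat("Bayesian cosinor mixed model - response:", x$response, "\n")
  cat("  ", length(x$design$y), "individuals,",
      length(x$draws$group_levels), "populations,",
      nrow(x$draws$draws), "posterior draws\n")
  cat("Posterior mean coefficients:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.cosinor_lmm <- function(object, ...) {
  colMeans(.fixed_draws(object))
}

#' Summarize a fitted cosinor mixed model
#'
#' Posterior mean, sd and 95% credible bounds for every parameter, plus
#' split R-hat and effective sample size, and the derived seasonal-rhythm
#' summaries (MESOR, amplitude, peak day) per sex at average size and
#' latitude.
#'
#' @param object A fitted [cosinor_lmm].
#' @param ... Unused.
#' @export
summary.cosinor_lmm <- function(object, ...) {
  d <- object$draws$draws
  tab <- data.frame(
    mean = colMeans(d), sd = apply(d, 2, stats::sd),
    q2.5 = apply(d, 2, stats::quantile, 0.025),
    q97.5 = apply(d, 2, stats::quantile, 0.975))
  conv <- object$convergence$report
  tab$rhat <- conv$rhat[match(rownames(tab), conv$parameter)]
  tab$ess <- conv$ess[match(rownames(tab), conv$parameter)]
  seas <- lapply(c(male = "male", female = "female"), function(s) {
    sd_ <- seasonal_draws(object, s)
    ap <- amplitude_phase(mean(sd_$beta_cos), mean(sd_$beta_sin))
    p <- cosinor_params(mean(sd_$mesor), ap$amplitude, ap$phase_rad,
                        object$design$period_days)
    ed <- if (ap$amplitude > 0) extremum_days(p) else c(peak_day = NA, trough_day = NA)
    c(mesor = p$mesor, amplitude = p$amplitude, peak_day = unname(ed[1]),
      trough_day = unname(ed[2]))
  })
  out <- list(response = object$response, coefficients = tab,
              seasonal = do.call(rbind, seas),
              variance = variance_fraction(object),
              convergence_pass = object$convergence$pass)
  class(out) <- "summary.cosinor_lmm"
  out
}

#' @export
print.summary.cosinor_lmm <- function(x, ...) {
  cat("Bayesian cosinor mixed model - response:", x$response, "\n\n")
  show <- x$coefficients[!grepl("^u_", rownames(x$coefficients)), ]
  print(round(show, 4))
  cat("\nSeasonal rhythm (model scale, at mean size/latitude):\n")
  print(round(x$seasonal, 3))
  cat(sprintf("\nAmong-population variance fraction: %.1f%% (95%% CI %.1f-%.1f%%)\n",
              x$variance$mean_pct, x$variance$ci_pct[1], x$variance$ci_pct[2]))
  cat("Convergence diagnostics:", if (x$convergence_pass) "pass" else "FAIL", "\n")
  invisible(x)
}

.profile_row <- function(fit, sex = "male", svl = NULL, latitude = NULL,
                         day = NULL) {
  st <- fit$design$standardization
  z_svl <- if (is.null(svl)) 0 else (svl - st$svl$center) / st$svl$scale
  z_lat <- if (is.null(latitude)) 0 else
    (latitude - st$lat$center) / st$lat$scale
  if (!is.null(svl) && (svl < st$svl$range[1] || svl > st$svl$range[2]))
    warning("SVL ", svl, " outside the modeled range (",
            paste(st$svl$range, collapse = "-"), "); extrapolating")
  if (!is.null(latitude) &&
      (latitude < st$lat$range[1] || latitude > st$lat$range[2]))
    warning("latitude ", latitude, " outside the modeled range; extrapolating")
  if (is.null(day)) {          # baseline profile: seasonal terms at the MESOR
    ct <- 0; st_ <- 0
  } else {
    cs <- cosinor_regressors(day, fit$design$period_days)
    ct <- cs[, "cos_t"]; st_ <- cs[, "sin_t"]
  }
  sf <- as.numeric(sex == "female")
  c(intercept = 1, cos_t = ct, sin_t = st_, sex_f = sf,
    std_svl = z_svl, std_lat = z_lat,
    cos_t_sex = ct * sf, sin_t_sex = st_ * sf,
    cos_t_svl = ct * z_svl, sin_t_svl = st_ * z_svl,
    cos_t_lat = ct * z_lat, sin_t_lat = st_ * z_lat)
}

#' Predict from a fitted cosinor mixed model
#'
#' @param object A fitted [cosinor_lmm].
#' @param newdata Optional data frame with the cohort covariate columns; the
#'   training data are used when omitted. Populations unseen in training get
#'   no random-intercept contribution (`u = 0`, the average population).
#' @param type `"mean"` for the posterior-mean linear predictor, `"draws"`
#'   for the full draws-by-rows matrix.
#' @param include_population Add the population intercept for known
#'   populations (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector (`"mean"`) or matrix of draws x rows (`"draws"`),
#'   on the model (log / ilr-coordinate) scale.
#' @export
predict.cosinor_lmm <- function(object, newdata = NULL,
                                type = c("mean", "draws"),
                                include_population = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$design$X
    grp <- as.character(object$design$group)
  } else {
    des <- build_design(newdata, object$response, object$design$period_days,
                        object$design$basis,
                        standardization = object$design$standardization,
                        check_rank = FALSE)
    X <- des$X
    grp <- as.character(des$group)
  }
  B <- .fixed_draws(object)
  mu <- B %*% t(X)                       # draws x rows
  if (include_population) {
    ucols <- paste0("u_", grp)
    known <- ucols %in% object$draws$parnames
    if (any(known)) {
      U <- object$draws$draws[, ucols[known], drop = FALSE]
      mu[, known] <- mu[, known] + U
    }
  }
  if (type == "draws") mu else colMeans(mu)
}

#' @export
fitted.cosinor_lmm <- function(object, ...) {
  predict(object, type = "mean")
}

#' @export
residuals.cosinor_lmm <- function(object, ...) {
  object$design$y - fitted(object)
}

#' Simulate posterior-predictive responses for cohort rows
#'
#' For each requested replicate, draws one posterior sample per row and adds
#' a fresh residual (and, for rows in unseen populations or when
#' `new_population = TRUE`, a fresh population effect), giving simulated
#' responses on the model scale.
#'
#' @param object A fitted [cosinor_lmm].
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param newdata Optional cohort rows (defaults to training data).
#' @param new_population Draw a fresh population effect for every row rather
#'   than reusing fitted intercepts.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.cosinor_lmm <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, new_population = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata = newdata, type = "draws",
                include_population = !new_population)
  nd <- nrow(mu); nr <- ncol(mu)
  sig <- object$draws$draws[, "sigma"]
  sigp <- object$draws$draws[, "sigma_pop"]
  out <- replicate(nsim, {
    k <- sample.int(nd, nr, replace = TRUE)
    eps <- stats::rnorm(nr, 0, sig[k])
    upop <- if (new_population) stats::rnorm(nr, 0, sigp[k]) else 0
    mu[cbind(k, seq_len(nr))] + upop + eps
  })
  as.data.frame(out)
}

#' Plot the fitted seasonal curve
#'
#' Posterior median and 95% credible band of the seasonal curve (model
#' scale, or original scale for log responses) across the year, by sex, at
#' average size and latitude, with the MESOR as a horizontal reference.
#'
#' @param x A fitted [cosinor_lmm].
#' @param sex `"male"`, `"female"`, or both.
#' @param original_scale Back-transform log responses to cells/microliter.
#' @param ... Passed to [graphics::plot].
#' @export
plot.cosinor_lmm <- function(x, sex = c("male", "female"),
                             original_scale = TRUE, ...) {
  sex <- match.arg(sex, several.ok = TRUE)
  days <- seq(1, x$design$period_days, by = 2)
  B <- .fixed_draws(x)
  bt <- function(v) if (original_scale && x$response_kind == "log") exp(v) else v
  curves <- lapply(sex, function(s) {
    Xp <- t(vapply(days, function(d) .profile_row(x, s, day = d),
                   numeric(ncol(B))))
    mu <- B %*% t(Xp)
    list(med = bt(apply(mu, 2, stats::median)),
         lo = bt(apply(mu, 2, stats::quantile, 0.025)),
         hi = bt(apply(mu, 2, stats::quantile, 0.975)))
  })
  ylim <- range(unlist(lapply(curves, function(c) c(c$lo, c$hi))))
  graphics::plot(NA, xlim = c(1, x$design$period_days), ylim = ylim,
                 xlab = "Day of year",
                 ylab = if (original_scale && x$response_kind == "log")
                   "WBC (cells/µl)" else x$response, ...)
  cols <- c("grey40", "grey70")[seq_along(sex)]
  for (i in seq_along(sex)) {
    graphics::polygon(c(days, rev(days)),
                      c(curves[[i]]$lo, rev(curves[[i]]$hi)),
                      col = grDevices::adjustcolor(cols[i], 0.3), border = NA)
    graphics::lines(days, curves[[i]]$med, col = cols[i], lwd = 2,
                    lty = i)
  }
  graphics::legend("topright", legend = sex, col = cols, lwd = 2,
                   lty = seq_along(sex), bty = "n")
  invisible(x)
}
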