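#' Posterior predictive draws for a new individual
#'
#' For every retained posterior draw, simulates the response of a new
#' individual with the given covariate profile: linear predictor plus a
#' fresh population effect `N(0, sigma_pop^2)` (when `new_population = TRUE`,
#' the default — a reference interval is meant to cover an individual from
#' any population in the range) plus a residual `N(0, sigma^2)`. With
#' `new_population = FALSE` and a `population` id, the fitted intercept of
#' that population is used instead (within-site screening).
#'
#' @param fit A fitted [cosinor_lmm].
#' @param sex `"male"` or `"female"`.
#' @param svl,latitude Covariates on their natural scales; `NULL` means the
#'   training-sample mean (z = 0). Values outside the modeled range trigger
#'   an extrapolation warning, not an error.
#' @param day Day of year; `NULL` evaluates the seasonal terms at the MESOR
#'   (cos = sin = 0), the baseline profile used for reference intervals.
#' @param n_new Independent new individuals per posterior draw.
#' @param new_population Draw a fresh population effect (default `TRUE`).
#' @param population Population id whose fitted intercept to reuse when
#'   `new_population = FALSE`.
#' @param seed Optional RNG seed.
#' @return Matrix of `n_new` rows by retained-draws columns, on the model
#'   scale (log-WBC or an ilr coordinate).
#' @export
posterior_predictive <- function(fit, sex = "male", svl = NULL,
                                 latitude = NULL, day = NULL, n_new = 1,
                                 new_population = TRUE, population = NULL,
                                 seed = NULL) {
  stopifnot(inherits(fit, "cosinor_lmm"))
  if (!is.null(seed)) set.seed(seed)
  xr <- .profile_row(fit, sex, svl, latitude, day)
  B <- .fixed_draws(fit)
  mu <- drop(B %*% xr)
  nd <- length(mu)
  sig <- fit$draws$draws[, "sigma"]
  if (new_population) {
    sigp <- fit$draws$draws[, "sigma_pop"]
    upop <- matrix(stats::rnorm(n_new * nd, 0, rep(sigp, each = n_new)),
                   n_new, nd)
  } else if (!is.null(population)) {
    ucol <- paste0("u_", population)
    if (!ucol %in% fit$draws$parnames)
      stop("unknown population: ", population)
    upop <- matrix(rep(fit$draws$draws[, ucol], each = n_new), n_new, nd)
  } else {
    upop <- 0
  }
  eps <- matrix(stats::rnorm(n_new * nd, 0, rep(sig, each = n_new)), n_new, nd)
  sweep(upop + eps, 2L, mu, "+")
}

#' Back-transform model-scale samples to the measurement scale
#'
#' Log-WBC samples are exponentiated to cells/microliter. For the leukocyte
#' differential, a matched matrix of samples from the four independently
#' fitted ilr-coordinate models (paired draw-by-draw) is jointly inverted to
#' the simplex and expressed as percentages per class.
#'
#' @param samples Numeric vector (`kind = "log"`) or a matrix with 4 columns
#'   of paired ilr-coordinate samples (`kind = "ilr"`).
#' @param kind `"log"` or `"ilr"`.
#' @param basis ilr contrast basis used by the fits.
#' @return Vector of cells/microliter, or a matrix of class percentages (one
#'   column per leukocyte class, rows summing to 100).
#' @export
back_transform <- function(samples, kind = c("log", "ilr"),
                           basis = ilr_basis(5)) {
  kind <- match.arg(kind)
  if (kind == "log") {
    return(exp(as.numeric(samples)))
  }
  samples <- as.matrix(samples)
  if (ncol(samples) != nrow(basis))
    stop("expected a matched ", nrow(basis),
         "-column matrix of ilr-coordinate samples")
  100 * ilr_inv(samples, basis)
}

#' Reference interval from predictive samples
#'
#' The baseline is the mode of the sample distribution, estimated by a
#' Gaussian kernel density (Silverman's bandwidth) maximized on a 512-point
#' grid over the sample range; the bounds are the empirical 2.5% and 97.5%
#' percentiles (or `(1 - level)/2` tails for other levels). Posterior
#' predictive distributions of back-transformed hematological variables are
#' right-skewed, so the interval is typically asymmetric about the mode.
#'
#' @param samples Numeric samples on the measurement scale.
#' @param level Coverage level in (0, 1), default 0.95.
#' @param variable,sex,units Optional labels carried in the result.
#' @return An object of class `reference_interval` with `mode`, `lower`,
#'   `upper`, `level`, `n` and the labels.
#' @export
reference_interval <- function(samples, level = 0.95, variable = NULL,
                               sex = NULL, units = NULL) {
  samples <- as.numeric(samples)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10)
    stop("at least 10 samples are required for a reference interval")
  if (length(samples) < 1000)
    warning("fewer than 1000 samples; interval estimates may be unstable")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  rng <- range(samples)
  mode_est <- if (diff(rng) == 0) rng[1] else {
    dd <- stats::density(samples, bw = "nrd0", n = 512, from = rng[1],
                         to = rng[2])
    dd$x[which.max(dd$y)]
  }
  qs <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(mode = mode_est, lower = qs[1], upper = qs[2],
                 level = level, n = length(samples),
                 variable = variable, sex = sex, units = units),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, digits = 4, ...) {
  lab <- paste(c(x$variable, if (!is.null(x$sex)) paste0("(", x$sex, ")")),
               collapse = " ")
  cat(sprintf("%s: mode %s, %g%% PI (%s - %s)%s  [n = %d]\n",
              if (nzchar(lab)) lab else "Reference interval",
              signif(x$mode, digits), 100 * x$level,
              signif(x$lower, digits), signif(x$upper, digits),
              if (!is.null(x$units)) paste0(" ", x$units) else "", x$n))
  invisible(x)
}

#' Probability of exceeding a multiple of a reference value
#'
#' Fraction of predictive samples above `threshold_multiplier` times the
#' reference (e.g. the RI mode): the chance of observing an individual that
#' far above baseline.
#'
#' @param samples Predictive samples on the measurement scale.
#' @param threshold_multiplier Multiplier applied to `reference`.
#' @param reference Positive reference value (typically the RI mode).
#' @return Probability in `[0, 1]`; vectorized over `threshold_multiplier`.
#' @export
exceedance_probability <- function(samples, threshold_multiplier = 1,
                                   reference) {
  if (!length(samples)) stop("'samples' is empty")
  if (reference <= 0) stop("'reference' must be positive")
  vapply(threshold_multiplier,
         function(m) mean(samples > m * reference), numeric(1))
}

#' Posterior contrast between parameter expressions
#'
#' Evaluates an expression over registered parameter names draw-wise and
#' summarizes the resulting posterior: mean, sd, and the posterior
#' probabilities that the contrast is positive or negative (draws exactly at
#' zero split evenly, so a degenerate all-zero contrast reports 0.5).
#'
#' @param fit A fitted [cosinor_lmm], or a `leuko_draws` object.
#' @param expr Character expression over parameter names (e.g. `"sex_f"` or
#'   `"(intercept + sex_f) - intercept"`). Parameter names are the design
#'   columns plus `u_<population>`, `sigma`, `sigma_pop`.
#' @param label Optional label for the result.
#' @return An object of class `posterior_contrast`: `mean`, `sd`,
#'   `prob_positive`, `prob_negative`, `draws`.
#' @export
contrast <- function(fit, expr, label = expr) {
  draws <- if (inherits(fit, "cosinor_lmm")) fit$draws else fit
  stopifnot(inherits(draws, "leuko_draws"))
  env <- as.list(as.data.frame(draws$draws))
  pe <- tryCatch(parse(text = expr), error = function(e)
    stop("cannot parse contrast expression: ", expr))
  vars <- all.vars(pe)
  unknown <- setdiff(vars, names(env))
  if (length(unknown))
    stop("unknown parameter name(s) in contrast: ",
         paste(unknown, collapse = ", "))
  d <- eval(pe[[1]], envir = env)
  contrast_from_draws(d, label)
}

#' @rdname contrast
#' @param d Numeric vector of draw-wise contrast values.
#' @export
contrast_from_draws <- function(d, label = NULL) {
  d <- as.numeric(d)
  p_pos <- mean(d > 0) + 0.5 * mean(d == 0)
  structure(list(label = label, mean = mean(d), sd = stats::sd(d),
                 prob_positive = p_pos, prob_negative = 1 - p_pos,
                 draws = d),
            class = "posterior_contrast")
}

#' @export
print.posterior_contrast <- function(x, digits = 3, ...) {
  cat(sprintf("%s: %s +/- %s   P(>0) = %.2f, P(<0) = %.2f\n",
              if (is.null(x$label)) "contrast" else x$label,
              signif(x$mean, digits), signif(x$sd, digits),
              x$prob_positive, x$prob_negative))
  invisible(x)
}

#' Draw-wise seasonal-rhythm quantities for one sex
#'
#' Combines the cosinor coefficients with their sex interactions to give,
#' per posterior draw, the sex-specific MESOR, linearized coefficients,
#' amplitude, acrophase, and peak day (at average size and latitude).
#'
#' @param fit A fitted [cosinor_lmm].
#' @param sex `"male"` or `"female"`.
#' @return List of draw vectors: `mesor`, `beta_cos`, `beta_sin`,
#'   `amplitude`, `phase_rad`, `peak_day` (fractional day in (0, tau]).
#' @export
seasonal_draws <- function(fit, sex = "male") {
  B <- .fixed_draws(fit)
  sf <- as.numeric(sex == "female")
  mesor <- B[, "intercept"] + sf * B[, "sex_f"]
  bc <- B[, "cos_t"] + sf * B[, "cos_t_sex"]
  bs <- B[, "sin_t"] + sf * B[, "sin_t_sex"]
  ap <- amplitude_phase(bc, bs)
  tau <- fit$design$period_days
  peak <- (-ap$phase_rad * tau / (2 * pi)) %% tau
  peak[peak == 0] <- tau
  list(mesor = mesor, beta_cos = bc, beta_sin = bs,
       amplitude = ap$amplitude, phase_rad = ap$phase_rad, peak_day = peak)
}

.wrap_day_diff <- function(d, tau = 365) {
  r <- d %% tau
  ifelse(r > tau / 2, r - tau, r)
}

#' Female-minus-male contrasts of the seasonal rhythm
#'
#' Draw-wise female-minus-male differences of the MESOR, amplitude and phase
#' (peak timing). For log responses the MESOR and amplitude contrasts are
#' reported on the original cells/microliter scale
#' (`exp(MESOR_f) - exp(MESOR_m)` and the difference of back-transformed
#' seasonal displacements); phase contrasts are in days, wrapped to
#' (-tau/2, tau/2].
#'
#' @param fit A fitted [cosinor_lmm].
#' @param original_scale Back-transform log responses (default `TRUE`).
#' @return Named list of [contrast_from_draws] results:
#'   `mesor`, `amplitude`, `phase_days`.
#' @export
sex_contrasts <- function(fit, original_scale = TRUE) {
  m <- seasonal_draws(fit, "male")
  f <- seasonal_draws(fit, "female")
  bt_log <- original_scale && fit$response_kind == "log"
  mesor_d <- if (bt_log) exp(f$mesor) - exp(m$mesor) else f$mesor - m$mesor
  amp_d <- if (bt_log) {
    (exp(f$mesor + f$amplitude) - exp(f$mesor)) -
      (exp(m$mesor + m$amplitude) - exp(m$mesor))
  } else f$amplitude - m$amplitude
  phase_d <- .wrap_day_diff(f$peak_day - m$peak_day, fit$design$period_days)
  list(mesor = contrast_from_draws(mesor_d, "MESOR female-male"),
       amplitude = contrast_from_draws(amp_d, "amplitude female-male"),
       phase_days = contrast_from_draws(phase_d, "phase (days) female-male"))
}

#' Does the seasonal swing exceed the reference-interval band?
#'
#' Draw-wise difference between the seasonal extremum's displacement from
#' baseline (the amplitude, back-transformed for log responses as
#' `exp(MESOR + A) - exp(MESOR)`) and the upper half-width of the reference
#' interval at the MESOR (`upper bound - mode`). A positive contrast means
#' the seasonal oscillation carries healthy individuals beyond the RI.
#'
#' @param fit A fitted [cosinor_lmm].
#' @param sex `"male"` or `"female"`.
#' @param ri Optional precomputed [reference_interval] on the measurement
#'   scale; computed from [posterior_predictive] when omitted.
#' @param seed Seed for the predictive simulation when `ri` is omitted.
#' @return A `posterior_contrast`; `prob_positive` is the posterior
#'   probability that the amplitude exceeds the RI half-width.
#' @export
amplitude_vs_ri <- function(fit, sex = "male", ri = NULL, seed = NULL) {
  s <- seasonal_draws(fit, sex)
  if (all(s$amplitude == 0))
    warning("amplitude is identically zero: degenerate contrast")
  if (is.null(ri)) {
    pp <- posterior_predictive(fit, sex = sex, seed = seed)
    samp <- if (fit$response_kind == "log") back_transform(pp, "log")
            else as.numeric(pp)
    ri <- reference_interval(samp, variable = fit$response, sex = sex)
  }
  half_width <- ri$upper - ri$mode
  disp <- if (fit$response_kind == "log")
    exp(s$mesor + s$amplitude) - exp(s$mesor) else s$amplitude
  contrast_from_draws(disp - half_width,
                      paste0("amplitude - RI half-width (", sex, ")"))
}

#' Observed fractions outside a reference interval
#'
#' @param values Observed measurements for the RI's variable and sex.
#' @param ri A [reference_interval] on the same scale.
#' @return Named vector: fraction `above` the upper bound (leukocytosis when
#'   the variable is WBC) and `below` the lower bound.
#' @export
observed_exceedance_fraction <- function(values, ri) {
  stopifnot(inherits(ri, "reference_interval"))
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no observations supplied")
  c(above = mean(values > ri$upper), below = mean(values < ri$lower))
}

#' Among-population fraction of unexplained variance
#'
#' Draw-wise `sigma_pop^2 / (sigma_pop^2 + sigma^2)`, the share of the
#' variation left after the fixed effects that is attributable to
#' among-population heterogeneity, summarized as a posterior mean percentage
#' with a credible interval.
#'
#' @param fit A fitted [cosinor_lmm] or `leuko_draws`.
#' @param level Credible level for the interval (default 0.95).
#' @return List with `mean_pct`, `ci_pct`, and the draw vector `fraction`.
#' @export
variance_fraction <- function(fit, level = 0.95) {
  draws <- if (inherits(fit, "cosinor_lmm")) fit$draws else fit
  stopifnot(inherits(draws, "leuko_draws"))
  s2p <- draws$draws[, "sigma_pop"]^2
  s2 <- draws$draws[, "sigma"]^2
  fr <- s2p / (s2p + s2)
  list(mean_pct = 100 * mean(fr),
       ci_pct = 100 * stats::quantile(fr, c((1 - level) / 2,
                                            1 - (1 - level) / 2),
                                      names = FALSE),
       fraction = fr)
}

#' Heterophil-to-lymphocyte ratio
#'
#' A standard leukocyte stress index (heterophils and lymphocytes respond
#' oppositely to glucocorticoids). Invariant to closure since it is a ratio
#' of parts.
#'
#' @param parts 5-part leukocyte composition in the order
#'   [leukocyte_classes] (any positive multiple).
#' @return `heterophils / lymphocytes`.
#' @examples
#' hl_ratio(c(0.8, 0.05, 0.05, 0.025, 0.075))
#' @export
hl_ratio <- function(parts) {
  if (length(parts) != 5L) stop("'parts' must have the 5 leukocyte classes")
  lym <- parts[[1]]; het <- parts[[4]]
  if (lym <= 0) stop("H:L ratio undefined: zero lymphocytes")
  het / lym
}
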