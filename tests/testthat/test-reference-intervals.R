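test_that("degenerate predictive draws collapse to the linear predictor", {
  fit <- fake_fit(rep(2, 500), sigma = 0, sigma_pop = 0)
  pp <- posterior_predictive(fit, sex = "male", seed = 1)
  expect_equal(as.numeric(pp), rep(2, 500))
  # sex profile shifts by the sex coefficient
  fit$draws$draws[, "sex_f"] <- 0.5
  ppf <- posterior_predictive(fit, sex = "female", seed = 1)
  expect_equal(as.numeric(ppf), rep(2.5, 500))
})

test_that("predictive variance decomposes into parameter, population and residual parts", {
  set.seed(4)
  fit <- fake_fit(rnorm(20000, 0, 0.3), sigma = 0.5, sigma_pop = 1)
  pp <- posterior_predictive(fit, sex = "male", seed = 2)
  expect_equal(var(as.numeric(pp)), 0.3^2 + 1 + 0.5^2, tolerance = 0.05)
  # without a new population effect only parameter + residual variance remain
  pp0 <- posterior_predictive(fit, sex = "male", new_population = FALSE,
                              seed = 2)
  expect_equal(var(as.numeric(pp0)), 0.3^2 + 0.5^2, tolerance = 0.02)
})

test_that("extrapolating covariate profiles warns rather than errors", {
  fit <- fake_fit(rep(1, 200), sigma = 0.1, sigma_pop = 0.1)
  expect_warning(posterior_predictive(fit, svl = 99, seed = 1),
                 "extrapolating")
  expect_silent(posterior_predictive(fit, svl = 60, seed = 1))
})

test_that("back-transformation restores measurement scales and closure", {
  expect_equal(back_transform(log(5000), "log"), 5000)
  expect_equal(unname(back_transform(matrix(0, 1, 4), "ilr")[1, ]),
               rep(20, 5))
  set.seed(12)
  z <- matrix(rnorm(400, 0, 1.5), 100, 4)
  pct <- back_transform(z, "ilr")
  expect_equal(rowSums(pct), rep(100, 100), tolerance = 1e-6)
  expect_true(all(pct > 0))
  expect_error(back_transform(matrix(0, 5, 3), "ilr"), "4-column")
})

test_that("reference intervals report the density mode and percentile bounds", {
  expect_warning(ri_const <- reference_interval(rep(7, 100)), "1000")
  expect_equal(c(ri_const$mode, ri_const$lower, ri_const$upper), c(7, 7, 7))
  expect_error(reference_interval(1:5), "at least 10")
  set.seed(5)
  x <- rnorm(100000)
  ri <- reference_interval(x)
  expect_lt(abs(ri$mode), 0.06)
  expect_equal(ri$lower, -1.96, tolerance = 0.04)
  expect_equal(ri$upper, 1.96, tolerance = 0.04)
  # right-skewed samples: asymmetric interval, mode < median < mean
  y <- exp(rnorm(100000, 0, 0.6))
  riy <- reference_interval(y)
  expect_lt(riy$mode, median(y))
  expect_lt(median(y), mean(y))
  expect_gt((riy$upper - riy$mode), (riy$mode - riy$lower))
  # nesting: a 99% interval contains the 95% interval
  ri99 <- reference_interval(y, level = 0.99)
  expect_lt(ri99$lower, riy$lower)
  expect_gt(ri99$upper, riy$upper)
})

test_that("exceedance probabilities count tail mass above multiples of the mode", {
  set.seed(6)
  x <- rnorm(50000, 10, 2)
  expect_equal(exceedance_probability(x, 1, median(x)), 0.5, tolerance = 0.01)
  p <- exceedance_probability(x, c(1, 1.2, 1.5, 10), 10)
  expect_true(all(diff(p) <= 0))
  expect_equal(p[4], 0)
  # log-normal oracle: P(X > mode) with mode exp(-1) for lnX ~ N(0,1)
  z <- exp(rnorm(2e5))
  expect_equal(exceedance_probability(z, 1, exp(-1)), pnorm(1),
               tolerance = 0.01)
  expect_error(exceedance_probability(numeric(0), 1, 1), "empty")
})

test_that("posterior contrasts summarize draw-wise differences and sign probabilities", {
  fit <- fake_fit(rnorm(1000, 2, 0.5))
  self <- contrast(fit, "sex_f - sex_f")
  expect_equal(self$mean, 0)
  expect_equal(self$sd, 0)
  expect_equal(self$prob_positive, 0.5)  # ties at zero split evenly
  d <- c(rep(1, 89), rep(-1, 11))
  ct <- contrast_from_draws(d)
  expect_equal(ct$prob_positive, 0.89)
  expect_equal(ct$prob_negative, 0.11)
  expect_error(contrast(fit, "not_a_parameter"), "unknown parameter")
  # expression route equals direct draw arithmetic
  fit$draws$draws[, "sex_f"] <- rnorm(1000)
  ct2 <- contrast(fit, "(intercept + sex_f) - intercept")
  expect_equal(ct2$mean, mean(fit$draws$draws[, "sex_f"]), tolerance = 1e-12)
})

test_that("draw-wise amplitude contrasts match a brute-force per-draw oracle", {
  sim <- simulate_cohort(small_config(), seed = 14)
  fit <- suppressWarnings(cosinor_lmm(sim$cohort, "log_wbc",
                                      mcmc = quick_mcmc(15, 300, 150)))
  m <- seasonal_draws(fit, "male")
  f <- seasonal_draws(fit, "female")
  B <- as.matrix(fit$draws)
  oracle_m <- sqrt(B[, "cos_t"]^2 + B[, "sin_t"]^2)
  oracle_f <- sqrt((B[, "cos_t"] + B[, "cos_t_sex"])^2 +
                   (B[, "sin_t"] + B[, "sin_t_sex"])^2)
  expect_equal(m$amplitude, unname(oracle_m), tolerance = 1e-12)
  expect_equal(f$amplitude, unname(oracle_f), tolerance = 1e-12)
  sc <- sex_contrasts(fit, original_scale = FALSE)
  expect_equal(sc$amplitude$draws, unname(oracle_f - oracle_m),
               tolerance = 1e-12)
  # phase contrasts are reported in wrapped days
  expect_true(all(abs(sc$phase_days$draws) <= 365 / 2))
})

test_that("amplitude-vs-RI contrasts point the right way in extreme regimes", {
  # seasonal swing far above the predictive spread: amplitude must win
  n <- 2000
  fit_hi <- fake_fit(rnorm(n, 2, 0.02), sigma = 0.05, sigma_pop = 0.02)
  fit_hi$draws$draws[, "cos_t"] <- 2 + rnorm(n, 0, 0.02)
  ct_hi <- amplitude_vs_ri(fit_hi, "male", seed = 3)
  expect_gt(ct_hi$prob_positive, 0.99)
  # near-zero amplitude cannot exceed a positive RI band
  fit_lo <- fake_fit(rnorm(n, 2, 0.02), sigma = 0.3, sigma_pop = 0.1)
  fit_lo$draws$draws[, "cos_t"] <- rnorm(n, 0, 0.005)
  ct_lo <- amplitude_vs_ri(fit_lo, "male", seed = 3)
  expect_lt(ct_lo$prob_positive, 0.01)
  # invariance under (bc, bs) -> (A, phi) -> (bc, bs) reparameterization
  s <- seasonal_draws(fit_hi, "male")
  lin <- linear_from_amplitude_phase(s$amplitude, s$phase_rad)
  expect_equal(lin$beta_cos, unname(fit_hi$draws$draws[, "cos_t"]),
               tolerance = 1e-10)
})

test_that("observed exceedance fractions count individuals outside the interval", {
  ri <- reference_interval(rnorm(5000, 0, 1))
  inside <- seq(-1.5, 1.5, length.out = 30)
  expect_equal(observed_exceedance_fraction(inside, ri),
               c(above = 0, below = 0))
  vals <- c(rep(0, 49), ri$upper + 1)
  expect_equal(observed_exceedance_fraction(vals, ri)[["above"]], 0.02)
  expect_error(observed_exceedance_fraction(numeric(0), ri), "no observations")
})

test_that("variance fractions follow sigma_pop^2 / (sigma_pop^2 + sigma^2) draw-wise", {
  fit <- fake_fit(rnorm(500), sigma = 0.7, sigma_pop = 0.7)
  expect_equal(variance_fraction(fit)$mean_pct, 50)
  fit0 <- fake_fit(rnorm(500), sigma = 0.7, sigma_pop = 0)
  expect_equal(variance_fraction(fit0)$mean_pct, 0)
})

test_that("the H:L ratio divides heterophils by lymphocytes, closure-free", {
  expect_equal(hl_ratio(c(0.8, 0.05, 0.05, 0.025, 0.075)), 0.03125)
  expect_equal(hl_ratio(c(0.3, 0.2, 0.1, 0.3, 0.1)), 1)
  x <- c(60, 10, 8, 15, 7)
  expect_equal(hl_ratio(x), hl_ratio(close_composition(x)))
  expect_error(hl_ratio(c(0, 1, 1, 1, 1)), "zero lymphocytes")
})

test_that("marginal class reference intervals are basis-independent", {
  sim <- simulate_cohort(small_config(), seed = 15)
  # second orthonormal basis: reversed part order
  V1 <- ilr_basis(5)
  V2 <- ilr_basis(5)[, 5:1]
  colnames(V2) <- leukocyte_classes
  get_ri <- function(V) {
    pct <- NULL
    std <- NULL
    coord <- sapply(1:4, function(k) {
      f <- suppressWarnings(
        cosinor_lmm(sim$cohort, paste0("ilr", k), basis = V,
                    mcmc = quick_mcmc(16, 400, 200), standardization = std))
      std <<- f$design$standardization
      as.numeric(posterior_predictive(f, sex = "male", seed = 100 + k))
    })
    apply(back_transform(coord, "ilr", V), 2, function(s)
      reference_interval(s)$mode)
  }
  m1 <- get_ri(V1)
  m2 <- get_ri(V2)
  expect_true(all(abs(m1 - m2) < 2))  # percentage points, Monte-Carlo slack
})
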