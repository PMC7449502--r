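sim_small <- simulate_cohort(small_config(), seed = 10)

test_that("identical seed and configuration reproduce draws bit-for-bit", {
  f1 <- suppressWarnings(cosinor_lmm(sim_small$cohort, "log_wbc",
                                     mcmc = quick_mcmc(3, 150, 100)))
  f2 <- suppressWarnings(cosinor_lmm(sim_small$cohort, "log_wbc",
                                     mcmc = quick_mcmc(3, 150, 100)))
  expect_identical(f1$draws$draws, f2$draws$draws)
  f3 <- suppressWarnings(cosinor_lmm(sim_small$cohort, "log_wbc",
                                     mcmc = quick_mcmc(4, 150, 100)))
  expect_false(identical(f1$draws$draws, f3$draws$draws))
})

test_that("flat data concentrate the posterior on a zero-effect model", {
  truth <- default_true_params()
  t0 <- truth$log_wbc
  t0$amplitude <- 0; t0$amplitude_female <- 0
  t0$beta_cos <- 0; t0$beta_sin <- 0
  t0$beta_cos_sex <- 0; t0$beta_sin_sex <- 0
  t0$beta_sex <- 0; t0$beta_svl <- 0; t0$beta_lat <- 0
  t0$beta_cos_svl <- 0; t0$beta_sin_svl <- 0
  t0$beta_cos_lat <- 0; t0$beta_sin_lat <- 0
  t0$sigma_pop <- 0; t0$sigma <- 0.3
  truth$log_wbc <- t0
  # design scale: 54 populations give the sigma_pop posterior room to collapse
  sim <- simulate_cohort(truth = truth, seed = 77)
  fit <- suppressWarnings(cosinor_lmm(sim$cohort, "log_wbc",
                                      mcmc = quick_mcmc(6)))
  cf_ <- coef(fit)
  expect_lt(max(abs(cf_[-1])), 0.12)
  expect_equal(unname(cf_["intercept"]),
               mean(log(sim$cohort$wbc_cells_per_ul)), tolerance = 0.02)
  # degenerate-variance recovery: sigma_pop posterior collapses toward 0
  sp <- fit$draws$draws[, "sigma_pop"]
  s <- fit$draws$draws[, "sigma"]
  expect_lt(quantile(sp, 0.95), 0.3 * mean(s))
})

test_that("posterior means track the REML mixed-model optimum under flat priors", {
  skip_if_not_installed("lme4")
  fit <- suppressWarnings(cosinor_lmm(sim_small$cohort, "log_wbc",
                                      mcmc = quick_mcmc(11, 800, 300)))
  des <- fit$design
  dd <- data.frame(des$X[, -1], y = des$y, g = des$group)
  form <- as.formula(paste("y ~", paste(colnames(des$X)[-1], collapse = "+"),
                           "+ (1 | g)"))
  ml <- lme4::lmer(form, data = dd, REML = TRUE)
  bhat <- lme4::fixef(ml)
  post <- coef(fit)
  post_sd <- apply(fit$draws$draws[, seq_along(post)], 2, sd)
  expect_true(all(abs(post - bhat) < pmax(0.02, 0.35 * post_sd)))
  vc <- as.data.frame(lme4::VarCorr(ml))
  expect_equal(mean(fit$draws$draws[, "sigma"]),
               vc$sdcor[vc$grp == "Residual"], tolerance = 0.08)
})

test_that("row order does not affect posterior summaries beyond Monte-Carlo error", {
  set.seed(99)
  perm <- sample(nrow(sim_small$cohort))
  f1 <- suppressWarnings(cosinor_lmm(sim_small$cohort, "log_wbc",
                                     mcmc = quick_mcmc(12, 600, 250)))
  f2 <- suppressWarnings(cosinor_lmm(sim_small$cohort[perm, ], "log_wbc",
                                     mcmc = quick_mcmc(12, 600, 250)))
  expect_true(all(abs(coef(f1) - coef(f2)) < 0.05))
})

test_that("convergence diagnostics separate mixed from unmixed chains", {
  # well-mixed: independent draws from one distribution in every chain
  set.seed(1)
  pn <- c("a", "b")
  good <- structure(list(
    draws = cbind(a = rnorm(3000), b = rnorm(3000, 5, 2)),
    chain = rep(1:3, each = 1000), iteration = rep(1:1000, 3),
    parnames = pn, n_fixed = 2L, group_levels = character(),
    prior = prior_spec(), mcmc = mcmc_config(3, 1000, 0)),
    class = "leuko_draws")
  cv <- check_convergence(good)
  expect_true(cv$pass)
  expect_true(all(abs(cv$report$rhat - 1) < 0.01))
  # chains centered at different values must fail loudly
  bad <- good
  bad$draws[, "a"] <- rnorm(3000, rep(c(0, 3, 6), each = 1000))
  cv_bad <- check_convergence(bad)
  expect_false(cv_bad$pass)
  expect_gt(cv_bad$report$rhat[1], 1.5)
  expect_identical(cv_bad$report$parameter[1], "a")  # worst first
  single <- good
  single$mcmc$n_chains <- 1L
  expect_error(check_convergence(single), "2 chains")
})

test_that("predict, fitted, residuals and simulate are mutually consistent", {
  fit <- suppressWarnings(cosinor_lmm(sim_small$cohort, "log_wbc",
                                      mcmc = quick_mcmc(13, 300, 150)))
  mu <- fitted(fit)
  expect_equal(length(mu), nrow(sim_small$cohort))
  expect_equal(residuals(fit), fit$design$y - mu)
  expect_lt(mean(abs(residuals(fit))), 2 * mean(fit$draws$draws[, "sigma"]))
  dr <- predict(fit, type = "draws")
  expect_equal(dim(dr), c(nrow(fit$draws$draws), nrow(sim_small$cohort)))
  expect_equal(colMeans(dr), mu)
  s <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(s), c(nrow(sim_small$cohort), 3L))
  # predictions for new rows reuse the stored standardization
  nd <- sim_small$cohort[1:5, ]
  expect_equal(predict(fit, newdata = nd), mu[1:5], tolerance = 1e-10)
})
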