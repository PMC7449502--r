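# shared fixtures: reduced study design for fast model fits, and a
# hand-built fitted object with known posterior draws for analytic checks

small_config <- function() {
  cf <- default_study_config()
  cf$n_populations <- 12L
  cf$region_sites <- c(north = 6L, central = 4L, south = 2L)
  cf$n_males <- 80L
  cf$n_females <- 60L
  cf
}

quick_mcmc <- function(seed = 1, n_draws = 400, burn_in = 200) {
  mcmc_config(n_chains = 3, n_draws = n_draws, burn_in = burn_in, seed = seed)
}

# cosinor_lmm-shaped object whose "posterior" is fully under test control
fake_fit <- function(intercept_draws, sigma = 0.5, sigma_pop = 1,
                     n_draws = length(intercept_draws)) {
  pn <- c("intercept", "cos_t", "sin_t", "sex_f", "std_svl", "std_lat",
          "cos_t_sex", "sin_t_sex", "cos_t_svl", "sin_t_svl",
          "cos_t_lat", "sin_t_lat", "u_P01", "sigma", "sigma_pop")
  d <- matrix(0, n_draws, length(pn), dimnames = list(NULL, pn))
  d[, "intercept"] <- intercept_draws
  d[, "sigma"] <- sigma
  d[, "sigma_pop"] <- sigma_pop
  draws <- structure(
    list(draws = d, chain = rep(1:2, length.out = n_draws),
         iteration = seq_len(n_draws), parnames = pn, n_fixed = 12L,
         group_levels = "P01", prior = prior_spec(),
         mcmc = mcmc_config(n_chains = 2, n_draws = ceiling(n_draws / 2),
                            burn_in = 0)),
    class = "leuko_draws")
  structure(
    list(draws = draws, response = "log_wbc", response_kind = "log",
         design = list(
           standardization = list(
             svl = list(center = 60, scale = 5, range = c(45, 80)),
             lat = list(center = 4.6e6, scale = 2e5,
                        range = c(4.2e6, 5.1e6))),
           period_days = 365)),
    class = "cosinor_lmm")
}

random_compositions <- function(n, D = 5, seed = 1) {
  set.seed(seed)
  g <- matrix(stats::rgamma(n * D, shape = 1.5), n, D)
  g / rowSums(g)
}
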