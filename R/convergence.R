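#' Split R-hat for one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#'
#' @param x Matrix of draws with one column per chain (equal lengths).
#' @return Scalar R-hat (1 at convergence; values above ~1.01 are suspect).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  mu <- colMeans(xs)
  s2 <- apply(xs, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size for one parameter
#'
#' Multi-chain effective sample size using chain-averaged autocorrelations
#' truncated by Geyer's initial positive sequence rule.
#'
#' @param x Matrix of draws with one column per chain.
#' @return Estimated effective number of independent draws.
#' @export
effective_sample_size <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  if (all(apply(x, 2, stats::var) == 0)) return(NA_real_)
  max_lag <- min(n - 1L, 500L)
  rho <- rowMeans(vapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(max_lag + 1L)))
  # Geyer: sum paired autocorrelations while the pair sums stay positive
  s <- 0
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Convergence diagnostics for posterior draws
#'
#' Computes split R-hat and effective sample size for every parameter and
#' declares a pass iff all R-hat values are below `rhat_max` and all
#' effective sample sizes are at least `ess_min`. Parameters are listed
#' worst-first by R-hat.
#'
#' @param draws A `leuko_draws` object from [gibbs_lmm] (or a fitted
#'   [cosinor_lmm]).
#' @param rhat_max R-hat pass threshold (default 1.01).
#' @param ess_min Minimum effective sample size per parameter (default 400).
#' @return List with `report` (data frame: parameter, rhat, ess, sorted by
#'   decreasing rhat), `pass`, and the thresholds.
#' @export
check_convergence <- function(draws, rhat_max = 1.01, ess_min = 400) {
  if (inherits(draws, "cosinor_lmm")) draws <- draws$draws
  stopifnot(inherits(draws, "leuko_draws"))
  if (draws$mcmc$n_chains < 2L)
    stop("convergence diagnostics require at least 2 chains")
  per_chain <- function(p) {
    matrix(draws$draws[, p], ncol = draws$mcmc$n_chains)
  }
  stats_ <- t(vapply(draws$parnames, function(p) {
    m <- per_chain(p)
    c(rhat = split_rhat(m), ess = effective_sample_size(m))
  }, c(rhat = 0, ess = 0)))
  report <- data.frame(parameter = draws$parnames,
                       rhat = stats_[, "rhat"], ess = stats_[, "ess"],
                       row.names = NULL)
  report <- report[order(-report$rhat), ]
  usable <- !is.na(report$rhat)
  pass <- all(report$rhat[usable] < rhat_max) &&
    all(report$ess[usable] >= ess_min)
  structure(list(report = report, pass = pass,
                 rhat_max = rhat_max, ess_min = ess_min),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, n = 6, ...) {
  cat("Convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(thresholds: R-hat < %.3g, ESS >= %g)\n", x$rhat_max, x$ess_min))
  cat("Worst parameters by R-hat:\n")
  print(utils::head(x$report, n), row.names = FALSE)
  invisible(x)
}
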