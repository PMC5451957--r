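# Joint validation of all MCMC conditional updates by comparing two
# simulators of the same prior-predictive distribution.

#' Successive-conditional validation of the profile-regression sampler
#'
#' Runs Geweke-style "getting it right" validation: a marginal-conditional
#' simulator (parameters from the prior, data from the model) and a
#' successive-conditional simulator (alternate the MCMC transition kernels
#' with re-simulation of data given the current parameters) target the same
#' distribution, so the moments of every parameter must agree up to Monte
#' Carlo error.  Compares means and variances of the DP concentration, the
#' residual standard deviation, and each selection weight.
#'
#' @param n_cycles Number of cycles/draws per simulator.
#' @param n_subjects,P,K Size of the synthetic data regenerated each cycle.
#' @param truncation_level Stick-breaking truncation.
#' @param n_confounders Number of standard-normal confounder columns in the
#'   fixed design.
#' @param sweeps_per_cycle MCMC sweeps between data re-simulations.
#' @param seed Integer seed.
#' @return A tibble with one row per (parameter, moment): simulator values,
#'   combined Monte Carlo standard error (batch-means on the dependent
#'   chain), and the absolute z-score `|diff| / se`.
#' @export
bpr_getting_it_right <- function(n_cycles = 5000, n_subjects = 25, P = 2,
                                 K = 2, truncation_level = 8,
                                 n_confounders = 1, sweeps_per_cycle = 2,
                                 seed = 1L) {
  set.seed(seed)
  n <- n_subjects
  W <- matrix(rnorm(n * n_confounders), n, n_confounders)
  rho <- matrix(1 / K, P, K)
  config <- bpr_config(truncation_level = truncation_level,
                       variable_selection = "continuous",
                       theta_prior = c(0, 2), beta_sd = 1,
                       sigma_prior = c(2.5, 2.5), seed = seed)
  priors <- bpr_priors(config, y = NULL, P = P, K = K, rho = rho)
  priors$theta_mu0 <- 0
  priors$theta_var0 <- 4
  priors$b_sigma <- 2.5  # fixed constant scale (not data-dependent here)
  pr <- c(priors, list(W_template = W))

  record <- function(state) {
    c(alpha = state$alpha, sigma = sqrt(state$sigma2),
      setNames(state$zeta, paste0("zeta_", seq_len(P))))
  }

  # marginal-conditional: iid prior draws
  mc <- matrix(NA_real_, n_cycles, 2 + P)
  for (b in seq_len(n_cycles)) {
    st <- bpr_prior_state(pr, n, P, K)
    mc[b, ] <- record(st)
  }
  colnames(mc) <- names(record(bpr_prior_state(pr, n, P, K)))

  # successive-conditional: kernel sweeps alternating with data simulation
  st <- bpr_prior_state(pr, n, P, K)
  sc <- matrix(NA_real_, n_cycles, 2 + P, dimnames = list(NULL, colnames(mc)))
  for (b in seq_len(n_cycles)) {
    dat <- bpr_simulate_data(st, priors, n, P, K, W)
    # the latents are drawn jointly with the fresh data and must replace
    # the old ones, or the state-data joint no longer targets the model
    st$z <- as.integer(dat$z)
    st$gamma <- dat$gamma
    data <- list(x = dat$x, K = as.integer(K), has_y = TRUE, y = dat$y, W = W)
    st <- bpr_kernel_cpp(data, priors, st, as.integer(sweeps_per_cycle))
    sc[b, ] <- record(st)
  }

  batch_se <- function(v) {
    nb <- max(10, floor(sqrt(length(v))))
    bs <- floor(length(v) / nb)
    means <- vapply(seq_len(nb), function(j) {
      mean(v[((j - 1) * bs + 1):(j * bs)])
    }, numeric(1))
    sd(means) / sqrt(nb)
  }

  rows <- list()
  for (par in colnames(mc)) {
    for (mom in c("mean", "var")) {
      f <- if (mom == "mean") identity else function(v) (v - mean(v))^2
      a <- f(mc[, par])
      b <- f(sc[, par])
      se <- sqrt(sd(a)^2 / n_cycles + batch_se(b)^2)
      rows[[length(rows) + 1]] <- tibble(
        parameter = par, moment = mom,
        marginal_conditional = mean(a),
        successive_conditional = mean(b),
        se = se,
        z = abs(mean(a) - mean(b)) / se)
    }
  }
  dplyr::bind_rows(rows)
}
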