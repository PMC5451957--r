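#' Configuration for Bayesian profile regression
#'
#' Settings for the outcome-supervised Dirichlet-process mixture model over
#' categorical exposure profiles.  Defaults follow common practice for this
#' model family: a truncated stick-breaking representation with a Gamma
#' hyperprior on the concentration parameter, weakly informative
#' Normal/Inverse-Gamma priors on the outcome sub-model, and a Beta(0.5, 0.5)
#' prior on the continuous variable-selection weights.
#'
#' @param n_burnin Number of burn-in sweeps discarded before retention.
#' @param n_sweeps Number of post-burn-in MCMC sweeps.
#' @param n_keep Number of draws retained (sweeps are thinned to this many;
#'   bounded memory regardless of `n_sweeps`).
#' @param truncation_level Number of components in the truncated
#'   stick-breaking representation.  Must comfortably exceed the plausible
#'   number of occupied clusters; the fit warns if occupied components
#'   approach the truncation.
#' @param dp_concentration_prior Length-2 numeric, Gamma (shape, rate) prior
#'   on the concentration parameter \eqn{\alpha}.
#' @param fix_alpha Optional numeric: when supplied, \eqn{\alpha} is held
#'   fixed at this value instead of being sampled (used for exact
#'   small-sample validation against partition enumeration).
#' @param dirichlet_mass Dirichlet mass per category for the within-cluster
#'   category probabilities.
#' @param outcome_included Should the outcome sub-model supervise the
#'   clustering?  When `FALSE` the mixture is fit to the profiles alone.
#' @param variable_selection `"none"` or `"continuous"`.  The continuous
#'   option mixes cluster-specific category probabilities with the observed
#'   marginal frequencies through a per-pesticide latent weight in (0, 1).
#' @param theta_prior Optional length-2 numeric (mean, sd) for the prior on
#'   cluster outcome means; default is (mean(y), 2 sd(y)).
#' @param beta_sd Prior standard deviation for confounder effects on the
#'   standardized confounder scale.
#' @param sigma_prior Length-2 numeric (shape, scale multiplier): the
#'   residual variance prior is Inverse-Gamma(shape, multiplier * var(y)).
#' @param zeta_prior Length-2 numeric Beta prior on selection weights.
#' @param zeta_step Random-walk standard deviation on logit selection
#'   weights.
#' @param seed Integer seed controlling all MCMC randomness.
#'
#' @return A list of class `bpr_config`.
#' @export
bpr_config <- function(n_burnin = 20000, n_sweeps = 200000, n_keep = 5000,
                       truncation_level = 50,
                       dp_concentration_prior = c(2, 1),
                       fix_alpha = NULL,
                       dirichlet_mass = 0.5,
                       outcome_included = TRUE,
                       variable_selection = c("continuous", "none"),
                       theta_prior = NULL,
                       beta_sd = 10,
                       sigma_prior = c(2.5, 2.5),
                       zeta_prior = c(0.5, 0.5),
                       zeta_step = 0.8,
                       seed = 1L) {
  variable_selection <- match.arg(variable_selection)
  cfg <- list(
    n_burnin = check_count(n_burnin, "n_burnin", min = 0L),
    n_sweeps = check_count(n_sweeps, "n_sweeps"),
    n_keep = check_count(n_keep, "n_keep"),
    truncation_level = check_count(truncation_level, "truncation_level", min = 2L),
    dp_concentration_prior = as.numeric(dp_concentration_prior),
    fix_alpha = fix_alpha,
    dirichlet_mass = as.numeric(dirichlet_mass),
    outcome_included = isTRUE(outcome_included),
    variable_selection = variable_selection,
    theta_prior = theta_prior,
    beta_sd = as.numeric(beta_sd),
    sigma_prior = as.numeric(sigma_prior),
    zeta_prior = as.numeric(zeta_prior),
    zeta_step = as.numeric(zeta_step),
    seed = as.integer(seed)
  )
  if (cfg$dirichlet_mass <= 0) abort("`dirichlet_mass` must be positive")
  structure(cfg, class = "bpr_config")
}

# Assemble the fixed prior/constant list handed to the C++ sampler.
bpr_priors <- function(config, y, P, K, rho) {
  theta_prior <- config$theta_prior
  if (is.null(theta_prior)) {
    if (is.null(y)) theta_prior <- c(0, 1) else {
      theta_prior <- c(mean(y), max(2 * sd(y), 1e-6))
    }
  }
  b_sigma <- if (is.null(y)) config$sigma_prior[2] else {
    config$sigma_prior[2] * max(var(y), 1e-12)
  }
  list(
    C = config$truncation_level,
    a_alpha = config$dp_concentration_prior[1],
    b_alpha = config$dp_concentration_prior[2],
    fix_alpha = !is.null(config$fix_alpha),
    a_phi = config$dirichlet_mass,
    theta_mu0 = theta_prior[1],
    theta_var0 = theta_prior[2]^2,
    beta_var = config$beta_sd^2,
    a_sigma = config$sigma_prior[1],
    b_sigma = b_sigma,
    var_select = identical(config$variable_selection, "continuous"),
    rho = rho,
    zeta_a = config$zeta_prior[1],
    zeta_b = config$zeta_prior[2],
    zeta_step = config$zeta_step
  )
}

# Draw a complete sampler state from the prior (also the initializer for
# fitting).  `alpha0` overrides the concentration draw when alpha is fixed.
bpr_prior_state <- function(priors, n, P, K, alpha0 = NULL) {
  C <- priors$C
  alpha <- if (priors$fix_alpha) alpha0 else rgamma(1, priors$a_alpha, priors$b_alpha)
  # sticks v ~ Beta(1, alpha) drawn in log space: 1 - v = U^(1/alpha)
  log1mv <- log(runif(C - 1)) / alpha
  logv <- log(-expm1(log1mv))
  w <- stick_weights_log(logv, log1mv)
  phi <- array(rgamma(C * P * K, priors$a_phi, 1), dim = c(C, P, K))
  phi <- phi / rep(apply(phi, c(1, 2), sum), times = K)
  theta <- rnorm(C, priors$theta_mu0, sqrt(priors$theta_var0))
  q <- ncol(priors$W_template %||% matrix(0, 1, 0))
  zeta <- rbeta(P, priors$zeta_a, priors$zeta_b)
  z <- sample.int(C, n, replace = TRUE, prob = w)
  gamma <- if (priors$var_select) {
    matrix(rbinom(n * P, 1, rep(zeta, each = n)), n, P)
  } else {
    matrix(1L, n, P)
  }
  list(
    z = as.integer(z),
    logv = logv,
    log1mv = log1mv,
    alpha = alpha,
    phi = phi,
    theta = theta,
    beta = rnorm(q, 0, sqrt(priors$beta_var)),
    sigma2 = 1 / rgamma(1, priors$a_sigma, priors$b_sigma),
    zeta = zeta,
    gamma = gamma
  )
}

stick_weights_log <- function(logv, log1mv) {
  C <- length(logv) + 1
  acc <- c(0, cumsum(log1mv))
  w <- exp(c(logv + acc[-C], acc[C]))
  w / sum(w)
}

# Simulate data from the model given a sampler state (fresh allocations and
# selection indicators are drawn from the state's weights); used by the
# successive-conditional validator.
bpr_simulate_data <- function(state, priors, n, P, K, W) {
  C <- priors$C
  w <- stick_weights_log(state$logv, state$log1mv)
  z <- sample.int(C, n, replace = TRUE, prob = w)
  gam <- if (priors$var_select) {
    matrix(rbinom(n * P, 1, rep(state$zeta, each = n)), n, P)
  } else {
    matrix(1L, n, P)
  }
  x <- matrix(0L, n, P)
  for (i in seq_len(n)) {
    for (p in seq_len(P)) {
      pr <- if (gam[i, p] == 1) state$phi[z[i], p, ] else priors$rho[p, ]
      x[i, p] <- sample.int(K, 1, prob = pr)
    }
  }
  mu <- state$theta[z]
  if (ncol(W) > 0) mu <- mu + as.vector(W %*% state$beta)
  y <- rnorm(n, mu, sqrt(state$sigma2))
  list(x = x, y = y, z = z, gamma = gam)
}

# Build a centered/standardized confounder design matrix from a data frame.
# Continuous columns (more than two distinct values) are centered at their
# mean and scaled to unit sd; factors/characters are expanded to treatment
# indicators; binary numerics are left on their 0/1 coding.
build_confounder_matrix <- function(confounders, n) {
  if (is.null(confounders)) {
    return(list(W = matrix(0, n, 0), centers = numeric(0), scales = numeric(0)))
  }
  cf <- as.data.frame(confounders)
  if (nrow(cf) != n) abort("confounder rows must match number of subjects")
  mm <- model.matrix(~., data = cf)
  W <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  centers <- setNames(numeric(ncol(W)), colnames(W))
  scales <- setNames(rep(1, ncol(W)), colnames(W))
  for (j in seq_len(ncol(W))) {
    col <- W[, j]
    if (length(unique(col)) > 2) {
      centers[j] <- mean(col)
      scales[j] <- ifelse(sd(col) > 0, sd(col), 1)
      W[, j] <- (col - centers[j]) / scales[j]
    }
  }
  if (ncol(W) > 0 && qr(W)$rank < ncol(W)) {
    warn("confounder design is rank deficient; the Gaussian prior on effects acts as a ridge stabilizer")
  }
  list(W = W, centers = centers, scales = scales)
}

#' Fit the outcome-supervised profile-regression mixture model
#'
#' Runs a blocked Gibbs sampler over a truncated stick-breaking
#' representation of a Dirichlet-process mixture of categorical exposure
#' profiles.  When an outcome is supplied, a Gaussian response sub-model with
#' cluster-specific means and global confounder effects supervises the
#' clustering ("outcome feedback"); continuous confounders are centered and
#' standardized internally before entering the model.
#'
#' @param profiles Data frame or integer matrix of categorical profiles,
#'   subjects in rows, exposures in columns, categories coded 1..K.
#' @param outcome Optional numeric outcome vector (e.g., FSIQ).  `NULL` fits
#'   the mixture without outcome feedback.
#' @param confounders Optional data frame of confounders (mixed
#'   discrete/continuous).
#' @param config A [bpr_config()] object.
#' @param K Number of categories per exposure (default: maximum observed).
#'
#' @return An object of class `bpr_fit` holding retained MCMC draws
#'   (`$draws`: allocations, cluster outcome means, confounder effects,
#'   residual variance, concentration, selection weights), the model inputs,
#'   and trace diagnostics.
#' @export
bpr_fit <- function(profiles, outcome = NULL, confounders = NULL,
                    config = bpr_config(), K = NULL) {
  x <- as.matrix(profiles)
  if (!is.numeric(x)) abort("`profiles` must be numeric categorical codes")
  storage.mode(x) <- "integer"
  n <- nrow(x)
  P <- ncol(x)
  if (is.null(K)) K <- max(x)
  if (any(x < 1L | x > K)) abort(sprintf("profile categories must lie in 1..%d", K))
  has_y <- !is.null(outcome) && config$outcome_included
  y <- NULL
  if (has_y) {
    y <- as.numeric(outcome)
    if (length(y) != n || any(!is.finite(y))) {
      abort("`outcome` must be finite and match the number of subjects")
    }
  }
  cm <- build_confounder_matrix(if (has_y) confounders else NULL, n)

  # observed marginal category frequencies (the mixing target for the
  # continuous variable-selection weights)
  rho <- t(vapply(seq_len(P), function(p) {
    tabulate(x[, p], nbins = K) / n
  }, numeric(K)))
  rho[rho == 0] <- 1e-12

  priors <- bpr_priors(config, y, P, K, rho)
  set.seed(config$seed)
  state <- bpr_prior_state(c(priors, list(W_template = cm$W)), n, P, K,
                           alpha0 = config$fix_alpha)
  data <- list(x = x, K = as.integer(K), has_y = has_y,
               y = if (has_y) y else numeric(0), W = cm$W)

  thin <- max(1L, as.integer(floor(config$n_sweeps / config$n_keep)))
  raw <- bpr_mcmc_cpp(data, priors, state,
                      as.integer(config$n_burnin),
                      as.integer(config$n_sweeps), thin)

  # transient singletons occasionally visit high component indices under a
  # Gamma-prior concentration, so judge truncation adequacy by the upper
  # quantile of the top occupied index, not its maximum
  if (quantile(raw$max_occupied, 0.99) > config$truncation_level - 5) {
    warn(sprintf(
      "occupied component index typically reaches %d with truncation %d; increase `truncation_level`",
      as.integer(quantile(raw$max_occupied, 0.99)), config$truncation_level))
  }

  colnames(raw$beta) <- colnames(cm$W)
  structure(list(
    draws = list(
      z = raw$z, theta = raw$theta, beta = raw$beta,
      sigma2 = raw$sigma2, alpha = raw$alpha, zeta = raw$zeta,
      n_occupied = raw$n_occupied, max_occupied = raw$max_occupied
    ),
    zeta_acc_rate = raw$final_state$zeta_acc_rate,
    profiles = x, outcome = y, K = K,
    confounders = cm, has_outcome = has_y,
    pesticides = colnames(profiles) %||% paste0("x", seq_len(P)),
    config = config
  ), class = "bpr_fit")
}

#' @export
print.bpr_fit <- function(x, ...) {
  cat(sprintf(
    "Profile-regression fit: %d subjects, %d exposures (K = %d), %s outcome\n",
    nrow(x$profiles), ncol(x$profiles), x$K,
    if (x$has_outcome) "with" else "without"))
  cat(sprintf("  %d retained draws; occupied clusters (median): %d\n",
              nrow(x$draws$z), median(x$draws$n_occupied)))
  invisible(x)
}

#' Tidy MCMC summaries of a profile-regression fit
#'
#' One row per scalar model parameter (confounder effects, residual sd,
#' concentration, and selection weights) with posterior mean and central 95%
#' interval.
#'
#' @param x A `bpr_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy bpr_fit
#' @export
tidy.bpr_fit <- function(x, ...) {
  summ <- function(v) c(mean(v), quantile(v, c(0.025, 0.975), names = FALSE))
  rows <- list()
  if (x$has_outcome) {
    for (j in seq_len(ncol(x$draws$beta))) {
      rows[[length(rows) + 1]] <- c(colnames(x$draws$beta)[j], summ(x$draws$beta[, j]))
    }
    rows[[length(rows) + 1]] <- c("sigma", summ(sqrt(x$draws$sigma2)))
  }
  rows[[length(rows) + 1]] <- c("alpha", summ(x$draws$alpha))
  if (identical(x$config$variable_selection, "continuous")) {
    for (p in seq_len(ncol(x$draws$zeta))) {
      rows[[length(rows) + 1]] <- c(paste0("zeta_", x$pesticides[p]),
                                    summ(x$draws$zeta[, p]))
    }
  }
  out <- do.call(rbind, rows)
  tibble(term = out[, 1],
         estimate = as.numeric(out[, 2]),
         conf.low = as.numeric(out[, 3]),
         conf.high = as.numeric(out[, 4]))
}

#' @method glance bpr_fit
#' @export
glance.bpr_fit <- function(x, ...) {
  tibble(
    n = nrow(x$profiles), n_exposures = ncol(x$profiles), K = x$K,
    n_draws = nrow(x$draws$z),
    n_sweeps = x$config$n_sweeps, n_burnin = x$config$n_burnin,
    outcome_included = x$has_outcome,
    median_occupied = median(x$draws$n_occupied),
    zeta_acc_rate = x$zeta_acc_rate %||% NA_real_
  )
}

#' Trace plot of confounder effects
#'
#' Convergence diagnostic: retained-draw traces for each confounder effect.
#'
#' @param fit A `bpr_fit` with outcome included.
#' @return A ggplot object.
#' @export
plot_bpr_traces <- function(fit) {
  stopifnot(inherits(fit, "bpr_fit"))
  if (!fit$has_outcome || ncol(fit$draws$beta) == 0) {
    abort("trace plots require a fit with outcome and confounders")
  }
  df <- as_tibble(fit$draws$beta)
  df$iteration <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -"iteration",
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = "confounder effect")
}
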