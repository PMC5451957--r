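#' Configuration for the kernel machine model
#'
#' Settings for Gaussian kernel machine regression with hierarchical
#' (grouped) variable selection.  The outcome is modeled as
#' `Y = h(z) + W beta + e` with `h` marginalized into a Gaussian term with
#' covariance `sigma^2 * lambda * K`, where
#' `K(z_i, z_j) = exp(-sum_p r_p (z_ip - z_jp)^2)` over the currently
#' selected exposures.  Each group carries a Bernoulli activity indicator
#' and an active group contributes exactly one member with nonzero
#' smoothness parameter, so correlated exposures sharing a group never enter
#' the same model.
#'
#' @param groups Named character vector or list mapping each exposure name
#'   to its group label (e.g., chemical class).
#' @param group_prior_prob Prior activity probability per group.
#' @param r_max Upper bound of the Uniform(0, r_max) prior on selected
#'   smoothness parameters.
#' @param lambda_prior Gamma (shape, rate) prior on the kernel variance
#'   ratio `lambda`.
#' @param sigma_prior Inverse-Gamma (shape, scale multiplier of var(y))
#'   prior on the residual variance.
#' @param beta_sd Prior sd of the fixed effects.
#' @param n_iter,n_burnin MCMC iterations kept / discarded.
#' @param r_step,lambda_step Log-scale random-walk proposal sds.
#' @param seed Integer seed.
#' @return A list of class `km_config`.
#' @export
km_config <- function(groups, group_prior_prob = 0.5, r_max = 100,
                      lambda_prior = c(1, 1), sigma_prior = c(2.5, 2.5),
                      beta_sd = 100, n_iter = 4000, n_burnin = 1000,
                      r_step = 0.6, lambda_step = 0.6, seed = 1L) {
  groups <- unlist(groups)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named mapping exposure -> group label")
  }
  if (group_prior_prob <= 0 || group_prior_prob >= 1) {
    abort("`group_prior_prob` must lie in (0, 1)")
  }
  structure(list(
    groups = groups, group_prior_prob = group_prior_prob,
    r_max = r_max, lambda_prior = lambda_prior, sigma_prior = sigma_prior,
    beta_sd = beta_sd,
    n_iter = check_count(n_iter, "n_iter"),
    n_burnin = check_count(n_burnin, "n_burnin", min = 0L),
    r_step = r_step, lambda_step = lambda_step, seed = as.integer(seed)
  ), class = "km_config")
}

#' Marginalized Gaussian log-likelihood of the kernel machine model
#'
#' `log N(y; W beta, sigma2 * (I + lambda K))`, evaluated through a Cholesky
#' factorization.
#'
#' @param y Outcome vector.
#' @param mu Mean vector (`W beta`).
#' @param sigma2 Residual variance.
#' @param lambda Kernel variance ratio.
#' @param K Kernel matrix.
#' @return Log-likelihood (scalar).
#' @export
km_marginal_loglik <- function(y, mu, sigma2, lambda, K) {
  n <- length(y)
  V <- diag(n) + lambda * K
  L <- chol(V)
  r <- y - mu
  w <- backsolve(L, r, transpose = TRUE)
  -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(L))) -
    0.5 * sum(w * w) / sigma2
}

# Kernel from per-exposure squared-distance matrices and smoothness values;
# with no selected exposure this is the all-ones matrix (the r -> 0 limit,
# a random intercept shared by all subjects).
km_kernel <- function(D, r) {
  n <- dim(D[[1]])[1]
  E <- matrix(0, n, n)
  for (p in seq_along(r)) if (r[p] > 0) E <- E + r[p] * D[[p]]
  exp(-E)
}

#' Fit the kernel machine model with hierarchical variable selection
#'
#' Metropolis-within-Gibbs sampler: conjugate updates for the fixed effects
#' and residual variance on the marginalized likelihood, log-scale random
#' walks for the kernel variance ratio and smoothness parameters, and
#' reversible activation / member-switch moves for the group and member
#' indicators (prior-draw proposals for the smoothness of a newly activated
#' member).  Exposures are standardized (mean 0, sd 1) internally.
#'
#' @param exposures Numeric matrix/data frame, subjects x exposures, with
#'   column names matching `config$groups`.
#' @param outcome Numeric outcome vector.
#' @param confounders Optional data frame of confounders (continuous
#'   columns centered and scaled internally).
#' @param config A [km_config()].
#' @return An object of class `km_fit` with draw matrices `delta`
#'   (group activity), `member` (selected member index per group, 0 when
#'   inactive), `r`, `lambda`, `sigma2`, `beta`, plus acceptance rates.
#' @export
km_fit <- function(exposures, outcome, confounders = NULL, config) {
  stopifnot(inherits(config, "km_config"))
  Z <- as.matrix(exposures)
  y <- as.numeric(outcome)
  n <- nrow(Z)
  if (length(y) != n) abort("outcome length must match exposures")
  nm <- colnames(Z)
  if (is.null(nm)) abort("`exposures` must have column names")
  missing_grp <- setdiff(nm, names(config$groups))
  if (length(missing_grp)) {
    abort(paste0("exposures without a group assignment: ",
                 paste(missing_grp, collapse = ", ")))
  }
  Z <- scale(Z)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  grp <- config$groups[nm]
  glev <- unique(unname(grp))
  G <- length(glev)
  members <- lapply(glev, function(g) which(grp == g))
  names(members) <- glev
  P <- ncol(Z)
  D <- lapply(seq_len(P), function(p) outer(Z[, p], Z[, p], "-")^2)

  cm <- build_confounder_matrix(confounders, n)
  W <- cbind(`(Intercept)` = 1, cm$W)
  q <- ncol(W)

  a_sig <- config$sigma_prior[1]
  b_sig <- config$sigma_prior[2] * max(var(y), 1e-12)
  la <- config$lambda_prior[1]
  lb <- config$lambda_prior[2]
  p_act <- config$group_prior_prob
  rmax <- config$r_max

  set.seed(config$seed)
  # initial state
  delta <- rbinom(G, 1, p_act)
  member <- integer(G)
  r <- numeric(P)
  for (g in seq_len(G)) {
    if (delta[g] == 1) {
      member[g] <- members[[g]][sample.int(length(members[[g]]), 1)]
      r[member[g]] <- runif(1, 0, rmax)
    }
  }
  lambda <- rgamma(1, la, lb)
  sigma2 <- var(y)
  beta <- c(mean(y), rep(0, q - 1))
  # track the kernel exponent E = sum_p r_p D_p; K = exp(-E) stays finite
  E <- matrix(0, n, n)
  for (p in seq_len(P)) if (r[p] > 0) E <- E + r[p] * D[[p]]
  K <- exp(-E)

  loglik <- function(beta, sigma2, lambda, K) {
    km_marginal_loglik(y, as.vector(W %*% beta), sigma2, lambda, K)
  }
  cur_ll <- loglik(beta, sigma2, lambda, K)

  tot <- config$n_burnin + config$n_iter
  keep0 <- config$n_burnin
  d_delta <- matrix(NA_integer_, config$n_iter, G, dimnames = list(NULL, glev))
  d_member <- matrix(NA_integer_, config$n_iter, G, dimnames = list(NULL, glev))
  d_r <- matrix(NA_real_, config$n_iter, P, dimnames = list(NULL, nm))
  d_lambda <- numeric(config$n_iter)
  d_sigma2 <- numeric(config$n_iter)
  d_beta <- matrix(NA_real_, config$n_iter, q, dimnames = list(NULL, colnames(W)))
  acc <- c(lambda = 0, r = 0, toggle = 0, switch = 0)
  try_ <- c(lambda = 0, r = 0, toggle = 0, switch = 0)

  for (it in seq_len(tot)) {
    # conjugate beta | sigma2, V0
    V0 <- diag(n) + lambda * K
    L <- chol(V0)
    Wt <- backsolve(L, W, transpose = TRUE)
    yt <- backsolve(L, y, transpose = TRUE)
    A <- crossprod(Wt) / sigma2
    diag(A) <- diag(A) + 1 / config$beta_sd^2
    bvec <- crossprod(Wt, yt) / sigma2
    La <- chol(A)
    mu_b <- backsolve(La, backsolve(La, bvec, transpose = TRUE))
    beta <- as.vector(mu_b + backsolve(La, rnorm(q)))
    # conjugate sigma2 | beta
    rt <- backsolve(L, y - as.vector(W %*% beta), transpose = TRUE)
    sigma2 <- 1 / rgamma(1, a_sig + n / 2, b_sig + 0.5 * sum(rt * rt))
    cur_ll <- loglik(beta, sigma2, lambda, K)

    # lambda: log-scale random walk
    lam_p <- lambda * exp(config$lambda_step * rnorm(1))
    ll_p <- loglik(beta, sigma2, lam_p, K)
    lacc <- ll_p - cur_ll + la * (log(lam_p) - log(lambda)) - lb * (lam_p - lambda)
    try_["lambda"] <- try_["lambda"] + 1
    if (log(runif(1)) < lacc) {
      lambda <- lam_p; cur_ll <- ll_p; acc["lambda"] <- acc["lambda"] + 1
    }

    # group toggles (activation draws member uniformly, r from its prior)
    for (g in seq_len(G)) {
      try_["toggle"] <- try_["toggle"] + 1
      if (delta[g] == 0) {
        mb <- members[[g]][sample.int(length(members[[g]]), 1)]
        r_new <- runif(1, 0, rmax)
        r_p <- r; r_p[mb] <- r_new
        E_p <- E + r_new * D[[mb]]
        K_p <- exp(-E_p)
        ll_p <- loglik(beta, sigma2, lambda, K_p)
        # member and r proposal densities cancel against their priors
        lacc <- ll_p - cur_ll + log(p_act) - log(1 - p_act)
        if (log(runif(1)) < lacc) {
          delta[g] <- 1L; member[g] <- mb; r <- r_p; E <- E_p; K <- K_p
          cur_ll <- ll_p; acc["toggle"] <- acc["toggle"] + 1
        }
      } else {
        mb <- member[g]
        r_p <- r; r_p[mb] <- 0
        E_p <- E - r[mb] * D[[mb]]
        K_p <- exp(-E_p)
        ll_p <- loglik(beta, sigma2, lambda, K_p)
        lacc <- ll_p - cur_ll + log(1 - p_act) - log(p_act)
        if (log(runif(1)) < lacc) {
          delta[g] <- 0L; member[g] <- 0L; r <- r_p; E <- E_p; K <- K_p
          cur_ll <- ll_p; acc["toggle"] <- acc["toggle"] + 1
        }
      }
    }

    # member switches within active multi-member groups
    for (g in which(delta == 1)) {
      mbs <- members[[g]]
      if (length(mbs) < 2) next
      try_["switch"] <- try_["switch"] + 1
      old <- member[g]
      new <- setdiff(mbs, old)[sample.int(length(mbs) - 1, 1)]
      r_new <- runif(1, 0, rmax)
      r_p <- r; r_p[old] <- 0; r_p[new] <- r_new
      E_p <- E - r[old] * D[[old]] + r_new * D[[new]]
      K_p <- exp(-E_p)
      ll_p <- loglik(beta, sigma2, lambda, K_p)
      if (log(runif(1)) < ll_p - cur_ll) {
        member[g] <- new; r <- r_p; E <- E_p; K <- K_p
        cur_ll <- ll_p; acc["switch"] <- acc["switch"] + 1
      }
    }

    # smoothness refinement for active members
    for (g in which(delta == 1)) {
      mb <- member[g]
      try_["r"] <- try_["r"] + 1
      r_new <- r[mb] * exp(config$r_step * rnorm(1))
      if (r_new >= rmax) next
      E_p <- E + (r_new - r[mb]) * D[[mb]]
      K_p <- exp(-E_p)
      ll_p <- loglik(beta, sigma2, lambda, K_p)
      lacc <- ll_p - cur_ll + log(r_new) - log(r[mb])  # log-scale Jacobian
      if (log(runif(1)) < lacc) {
        r[mb] <- r_new; E <- E_p; K <- K_p
        cur_ll <- ll_p; acc["r"] <- acc["r"] + 1
      }
    }

    if (it > keep0) {
      j <- it - keep0
      d_delta[j, ] <- delta
      d_member[j, ] <- member
      d_r[j, ] <- r
      d_lambda[j] <- lambda
      d_sigma2[j] <- sigma2
      d_beta[j, ] <- beta
    }
  }

  structure(list(
    delta = d_delta, member = d_member, r = d_r, lambda = d_lambda,
    sigma2 = d_sigma2, beta = d_beta,
    groups = grp, group_levels = glev, members = members,
    exposure_names = nm,
    acceptance = ifelse(try_ > 0, acc / try_, NA_real_),
    config = config
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kernel machine fit: %d exposures in %d groups, %d kept draws\n",
              length(x$exposure_names), length(x$group_levels), nrow(x$delta)))
  invisible(x)
}

#' Posterior inclusion probabilities (group and conditional)
#'
#' Group PIP: fraction of draws in which the group is active.  Conditional
#' PIP: among draws where the group is active, the fraction selecting each
#' member (these sum to 1 within a group).  Groups never active get `NA`
#' conditional PIPs (undefined, not zero).
#'
#' @param fit A `km_fit`.
#' @return A list of class `pip_report` with tibbles `group_pips`
#'   (`group`, `pip`, ranked descending) and `conditional_pips`
#'   (`group`, `exposure`, `conditional_pip`).
#' @export
pip_report <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  if (nrow(fit$delta) < 1) abort("no retained draws")
  gp <- tibble(group = fit$group_levels,
               pip = colMeans(fit$delta))
  gp <- gp[order(-gp$pip, gp$group), ]
  cp <- list()
  for (g in fit$group_levels) {
    active <- fit$delta[, g] == 1
    mbs <- fit$members[[g]]
    if (!any(active)) {
      cpv <- rep(NA_real_, length(mbs))
    } else {
      sel <- fit$member[active, g]
      cpv <- vapply(mbs, function(m) mean(sel == m), numeric(1))
    }
    cp[[g]] <- tibble(group = g,
                      exposure = fit$exposure_names[mbs],
                      conditional_pip = cpv)
  }
  structure(list(group_pips = gp,
                 conditional_pips = dplyr::bind_rows(cp)),
            class = "pip_report")
}

#' @export
print.pip_report <- function(x, ...) {
  cat("Group posterior inclusion probabilities:\n")
  print(as.data.frame(x$group_pips), row.names = FALSE)
  cat("\nConditional PIPs within groups:\n")
  print(as.data.frame(x$conditional_pips), row.names = FALSE)
  invisible(x)
}

#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  pr <- pip_report(x)
  dplyr::left_join(pr$conditional_pips, pr$group_pips, by = "group")
}

#' @method glance km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n_draws = nrow(x$delta),
         n_groups = length(x$group_levels),
         n_exposures = length(x$exposure_names),
         mean_lambda = mean(x$lambda),
         acc_lambda = unname(x$acceptance["lambda"]),
         acc_toggle = unname(x$acceptance["toggle"]))
}
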