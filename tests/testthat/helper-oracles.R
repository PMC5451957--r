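# Independent oracles used across tests.  These stay deliberately naive
# (enumeration, double loops, direct dense algebra) so they share no code
# with the implementation they check.

# All set partitions of n items as restricted-growth strings.
set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1]] <<- rgs[1:n]
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxv, v))
    }
  }
  recurse(1, 0)
  out
}

# Exact co-clustering probabilities under a Chinese-restaurant prior with
# fixed concentration and a Dirichlet-multinomial marginal likelihood.
exact_coclustering <- function(x, K, alpha, mass) {
  n <- nrow(x)
  P <- ncol(x)
  parts <- set_partitions(n)
  logw <- vapply(parts, function(z) {
    B <- max(z)
    lw <- B * log(alpha)
    for (b in seq_len(B)) {
      members <- which(z == b)
      lw <- lw + lgamma(length(members))
      for (p in seq_len(P)) {
        cnt <- tabulate(x[members, p], nbins = K)
        lw <- lw + lgamma(K * mass) - lgamma(K * mass + length(members)) +
          sum(lgamma(mass + cnt) - lgamma(mass))
      }
    }
    lw
  }, numeric(1))
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (k in seq_along(parts)) {
    S <- S + w[k] * outer(parts[[k]], parts[[k]], "==")
  }
  S
}

# Brute-force double-loop Moran's I statistics.
moran_global_loop <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  num <- 0
  S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
      S0 <- S0 + W[i, j]
    }
  }
  (n / S0) * num / sum(z^2)
}

moran_local_loop <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  m2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + W[i, j] * z[j]
    out[i] <- z[i] * s / m2
  }
  out
}

# Direct dense multivariate-normal log density (solve + determinant),
# independent of the Cholesky path used in the implementation.
dense_mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  as.numeric(
    -0.5 * n * log(2 * pi) -
      0.5 * determinant(Sigma, logarithm = TRUE)$modulus -
      0.5 * crossprod(r, solve(Sigma, r)))
}

# Small standard fixtures
unit_square <- function(side = 1) {
  cbind(c(0, side, side, 0), c(0, 0, side, side))
}

quick_bpr_config <- function(...) {
  bpr_config(n_burnin = 200, n_sweeps = 2000, n_keep = 500, ...)
}
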