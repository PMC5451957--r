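# Internal helpers shared across modules.

# Deterministic derivation of per-stage seeds from one master seed, kept
# below 2^31 so they remain valid R integers.
derive_seed <- function(master_seed, stage_index) {
  as.integer((as.numeric(master_seed) * 101L + stage_index * 7919) %% 2147483647)
}

# Empirical quartile cut points, linear-interpolation definition (type 7).
quartile_cuts <- function(x) {
  unname(quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE))
}

# Assign categories by half-open bins (-Inf, q25], (q25, q50], (q50, q75],
# (q75, Inf).  Duplicated cut points collapse categories deterministically
# (the lowest applicable category wins).
bin_by_cuts <- function(x, cuts) {
  cat <- rep(1L, length(x))
  for (ct in cuts) cat <- cat + (x > ct)
  as.integer(cat)
}

# Lower median: middle order statistic for odd n, lower-middle for even n.
lower_median <- function(x) {
  s <- sort(x)
  s[[floor((length(s) + 1) / 2)]]
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

as_date_safe <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(d) || anyNA(d)) abort(sprintf("unparseable date in %s", what))
  d
}
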