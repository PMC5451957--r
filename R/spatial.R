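#' Spatial neighbor weights for point data
#'
#' Builds an n x n nonnegative weight matrix with zero diagonal under one of
#' three schemes: symmetric-by-construction `k-nearest` (the default for
#' irregular residence points; guarantees no islands), `distance-band`
#' (weight 1 within a distance threshold; isolated points are an error), or
#' `rook-on-grid` (requires integer grid coordinates; neighbors share an
#' edge).
#'
#' @param coords Two-column matrix/data frame of planar coordinates.
#' @param scheme `"k-nearest"`, `"distance-band"`, or `"rook-on-grid"`.
#' @param k Number of neighbors (k-nearest).
#' @param band_m Distance threshold in meters (distance-band).
#' @param row_standardize Divide each row by its sum?
#' @return An object of class `spatial_weights`: list with `W`, `scheme`,
#'   `row_standardized`, `S0` (the weight sum).
#' @export
spatial_weights <- function(coords,
                            scheme = c("k-nearest", "distance-band", "rook-on-grid"),
                            k = 8, band_m = NULL, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  xy <- as.matrix(coords)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 3) abort("need at least 3 points")
  W <- matrix(0, n, n)
  if (scheme == "k-nearest") {
    if (k >= n) abort("`k` must be smaller than the number of points")
    d <- as.matrix(stats::dist(xy))
    for (i in seq_len(n)) {
      ord <- order(d[i, -i])  # deterministic tie-break by index order
      nb <- setdiff(seq_len(n), i)[ord[seq_len(k)]]
      W[i, nb] <- 1
    }
  } else if (scheme == "distance-band") {
    if (is.null(band_m) || band_m <= 0) abort("`band_m` must be positive")
    d <- as.matrix(stats::dist(xy))
    W <- (d > 0 & d <= band_m) * 1
    isl <- which(rowSums(W) == 0)
    if (length(isl)) {
      abort(sprintf("distance-band weights leave islands at point(s) %s",
                    paste(isl, collapse = ", ")))
    }
  } else {
    g <- round(xy)
    if (max(abs(xy - g)) > 1e-8) {
      abort("rook-on-grid requires integer grid coordinates")
    }
    for (i in seq_len(n)) {
      nb <- which(abs(g[, 1] - g[i, 1]) + abs(g[, 2] - g[i, 2]) == 1)
      W[i, nb] <- 1
    }
  }
  if (row_standardize) {
    rs <- rowSums(W)
    if (any(rs == 0)) abort("island point with no neighbor")
    W <- W / rs
  }
  structure(list(W = W, scheme = scheme, row_standardized = row_standardize,
                 S0 = sum(W)),
            class = "spatial_weights")
}

morans_i_stat <- function(z, W, S0) {
  n <- length(z)
  (n / S0) * as.numeric(crossprod(z, W %*% z)) / sum(z * z)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` on mean-centered
#' values, with expectation `-1/(n-1)` under no autocorrelation and a
#' two-sided permutation p-value
#' `p = (1 + #(|I*| >= |I|)) / (n_perm + 1)` from random relabelings.
#'
#' @param values Numeric vector (non-constant).
#' @param weights A [spatial_weights()] object.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return A tibble with `I`, `expected_I`, `p_value`, `n`, `n_perm`.
#' @export
global_morans_i <- function(values, weights, n_perm = 9999, seed = 1L) {
  stopifnot(inherits(weights, "spatial_weights"))
  z <- as.numeric(values) - mean(values)
  n <- length(z)
  if (nrow(weights$W) != n) abort("values and weights dimensions differ")
  if (sd(values) == 0) abort("zero variance: values are constant")
  I <- morans_i_stat(z, weights$W, weights$S0)
  set.seed(seed)
  Istar <- vapply(seq_len(n_perm), function(b) {
    morans_i_stat(z[sample.int(n)], weights$W, weights$S0)
  }, numeric(1))
  p <- (1 + sum(abs(Istar) >= abs(I))) / (n_perm + 1)
  tibble(I = I, expected_I = -1 / (n - 1), p_value = p,
         n = n, n_perm = as.integer(n_perm))
}

#' Local Moran's I with conditional permutation inference
#'
#' `I_i = (z_i / m2) * sum_j w_ij z_j` with `m2 = sum z^2 / n`; p-values use
#' conditional permutation (hold `i` fixed, permute the remaining values
#' among the other locations), two-sided on `|I_i|`, with optional
#' Benjamini-Hochberg adjustment.
#'
#' @param values Numeric vector.
#' @param weights A [spatial_weights()] object.
#' @param n_perm Number of conditional permutations per point.
#' @param seed Integer seed.
#' @param adjust Apply Benjamini-Hochberg adjustment across points?
#' @return A tibble with `i`, `I_i`, `p_value` (and `p_adjusted` when
#'   requested).
#' @export
local_morans_i <- function(values, weights, n_perm = 999, seed = 1L,
                           adjust = FALSE) {
  stopifnot(inherits(weights, "spatial_weights"))
  z <- as.numeric(values) - mean(values)
  n <- length(z)
  if (sd(values) == 0) abort("zero variance: values are constant")
  m2 <- sum(z * z) / n
  W <- weights$W
  lag <- as.vector(W %*% z)
  Ii <- z * lag / m2
  set.seed(seed)
  pv <- numeric(n)
  for (i in seq_len(n)) {
    others <- z[-i]
    wrow <- W[i, -i]
    nz <- wrow != 0
    stat <- abs(Ii[i])
    cnt <- 0
    for (b in seq_len(n_perm)) {
      perm <- sample(others)
      Istar <- z[i] * sum(wrow[nz] * perm[which(nz)]) / m2
      if (abs(Istar) >= stat) cnt <- cnt + 1
    }
    pv[i] <- (1 + cnt) / (n_perm + 1)
  }
  out <- tibble(i = seq_len(n), I_i = Ii, p_value = pv)
  if (adjust) out$p_adjusted <- stats::p.adjust(pv, method = "BH")
  out
}

#' Gaussian kernel density surface of point locations
#'
#' Evaluates a Gaussian-kernel density estimate on a regular grid padded by
#' at least four bandwidths around the points, so the raster integrates to
#' one (within numerical quadrature error).
#'
#' @param points Two-column matrix/data frame of planar coordinates.
#' @param bandwidth_m Gaussian kernel standard deviation in meters (> 0).
#' @param grid_n Number of grid nodes per axis.
#' @param pad_bandwidths Grid padding in bandwidth units.
#' @return A list of class `kde_surface` with `x`, `y` (grid node vectors)
#'   and `z` (density matrix, x by y).
#' @export
kde_surface <- function(points, bandwidth_m, grid_n = 128,
                        pad_bandwidths = 4) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(xy) < 1) abort("need at least one point")
  if (!is.numeric(bandwidth_m) || bandwidth_m <= 0) {
    abort("`bandwidth_m` must be positive")
  }
  pad <- pad_bandwidths * bandwidth_m
  lims <- c(min(xy[, 1]) - pad, max(xy[, 1]) + pad,
            min(xy[, 2]) - pad, max(xy[, 2]) + pad)
  # MASS::kde2d scales its bandwidth argument by 1/4 internally
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * bandwidth_m, n = grid_n,
                    lims = lims)
  structure(list(x = kd$x, y = kd$y, z = kd$z, bandwidth_m = bandwidth_m),
            class = "kde_surface")
}

#' @method autoplot kde_surface
#' @export
autoplot.kde_surface <- function(object, ...) {
  df <- tidyr::expand_grid(xi = seq_along(object$x), yi = seq_along(object$y))
  df$x <- object$x[df$xi]
  df$y <- object$y[df$yi]
  df$density <- object$z[cbind(df$xi, df$yi)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", fill = "density")
}
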