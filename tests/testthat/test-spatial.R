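test_that("weight schemes build valid neighbor structures", {
  set.seed(1)
  xy <- cbind(runif(30, 0, 1000), runif(30, 0, 1000))
  w <- spatial_weights(xy, "k-nearest", k = 5)
  expect_equal(diag(w$W), rep(0, 30))
  expect_equal(rowSums(w$W), rep(1, 30))  # row-standardized
  wu <- spatial_weights(xy, "k-nearest", k = 5, row_standardize = FALSE)
  expect_true(all(rowSums(wu$W) == 5))
  # distance-band islands are named errors
  far <- rbind(xy, c(1e6, 1e6))
  expect_error(spatial_weights(far, "distance-band", band_m = 300), "island")
  # rook on an integer grid
  g <- as.matrix(expand.grid(1:4, 1:4))
  wr <- spatial_weights(g, "rook-on-grid", row_standardize = FALSE)
  expect_true(all(rowSums(wr$W) %in% 2:4))
  expect_equal(wr$W, t(wr$W))
})

test_that("global Moran's I matches the double-loop oracle and expectation", {
  # perfect checkerboard on a 4x4 rook grid is strongly negative
  g <- as.matrix(expand.grid(1:4, 1:4))
  vals <- (-1)^(g[, 1] + g[, 2])
  w <- spatial_weights(g, "rook-on-grid", row_standardize = FALSE)
  res <- global_morans_i(vals, w, n_perm = 499, seed = 2)
  expect_equal(res$I, moran_global_loop(vals, w$W), tolerance = 1e-12)
  expect_lt(res$I, res$expected_I)
  expect_equal(res$expected_I, -1 / 15)
  # expectation closed form at n = 255
  set.seed(3)
  xy <- cbind(runif(255), runif(255))
  w255 <- spatial_weights(xy, "k-nearest", k = 8)
  r255 <- global_morans_i(rnorm(255), w255, n_perm = 99, seed = 4)
  expect_equal(r255$expected_I, -1 / 254)
  # oracle agreement on random fixtures, both weight styles
  set.seed(5)
  for (r in 1:5) {
    n <- 20 + r
    xy <- cbind(runif(n), runif(n))
    v <- rnorm(n)
    for (std in c(TRUE, FALSE)) {
      ww <- spatial_weights(xy, "k-nearest", k = 4, row_standardize = std)
      expect_equal(global_morans_i(v, ww, n_perm = 19, seed = 1)$I,
                   moran_global_loop(v, ww$W), tolerance = 1e-12)
    }
  }
  expect_error(global_morans_i(rep(1, 30),
                               spatial_weights(cbind(runif(30), runif(30)),
                                               "k-nearest", k = 4),
                               n_perm = 19, seed = 1),
               "zero variance")
})

test_that("Moran's I is invariant to positive affine transforms of values", {
  set.seed(6)
  xy <- cbind(runif(40), runif(40))
  v <- rnorm(40)
  w <- spatial_weights(xy, "k-nearest", k = 6)
  base <- global_morans_i(v, w, n_perm = 19, seed = 1)$I
  expect_equal(global_morans_i(3 + 2 * v, w, n_perm = 19, seed = 1)$I, base,
               tolerance = 1e-12)
})

test_that("local Moran's I satisfies the sum identity and sign logic", {
  set.seed(7)
  for (r in 1:10) {
    n <- 15 + 2 * r
    xy <- cbind(runif(n), runif(n))
    v <- rnorm(n)
    w <- spatial_weights(xy, "k-nearest", k = 4,
                         row_standardize = r %% 2 == 0)
    loc <- local_morans_i(v, w, n_perm = 19, seed = 1)
    glob <- global_morans_i(v, w, n_perm = 19, seed = 1)
    expect_equal(sum(loc$I_i), w$S0 * glob$I, tolerance = 1e-10)
    expect_equal(loc$I_i, moran_local_loop(v, w$W), tolerance = 1e-12)
  }
  # a single extreme point surrounded by opposite-signed neighbors
  g <- as.matrix(expand.grid(1:3, 1:3))
  vv <- rep(-1, 9)
  vv[5] <- 8
  wg <- spatial_weights(g, "rook-on-grid")
  locg <- local_morans_i(vv, wg, n_perm = 49, seed = 2)
  expect_lt(locg$I_i[5], 0)
  # BH adjustment flag adds a column
  expect_true("p_adjusted" %in%
                names(local_morans_i(vv, wg, n_perm = 19, seed = 1,
                                     adjust = TRUE)))
})

test_that("permutation p-values are reproducible and seed-sensitive", {
  set.seed(8)
  xy <- cbind(runif(35), runif(35))
  v <- rnorm(35)
  w <- spatial_weights(xy, "k-nearest", k = 5)
  p1 <- global_morans_i(v, w, n_perm = 199, seed = 42)$p_value
  p2 <- global_morans_i(v, w, n_perm = 199, seed = 42)$p_value
  expect_identical(p1, p2)
})

test_that("KDE surface integrates to one with the right modes", {
  # single point: mode at the nearest grid node
  k1 <- kde_surface(cbind(100, 200), bandwidth_m = 50, grid_n = 64)
  peak <- which(k1$z == max(k1$z), arr.ind = TRUE)
  expect_equal(k1$x[peak[1]], 100, tolerance = 5)
  expect_equal(k1$y[peak[2]], 200, tolerance = 5)
  # quadrature: integral within 2% on a padded grid
  set.seed(9)
  pts <- cbind(rnorm(40, 0, 300), rnorm(40, 0, 300))
  kk <- kde_surface(pts, bandwidth_m = 150, grid_n = 128)
  cell <- diff(kk$x[1:2]) * diff(kk$y[1:2])
  expect_equal(sum(kk$z) * cell, 1, tolerance = 0.02)
  # two distant identical points: two equal-height modes
  k2 <- kde_surface(rbind(c(0, 0), c(5000, 0)), bandwidth_m = 100,
                    grid_n = 256)
  expect_equal(max(k2$z[k2$x < 2500, ]), max(k2$z[k2$x >= 2500, ]),
               tolerance = 1e-6)
  expect_error(kde_surface(cbind(0, 0), bandwidth_m = 0), "positive")
})

test_that("Moran's I type-I error is calibrated under the null", {
  set.seed(10)
  rejections <- replicate(200, {
    n <- 50
    xy <- cbind(runif(n), runif(n))
    w <- spatial_weights(xy, "k-nearest", k = 8)
    global_morans_i(rnorm(n), w, n_perm = 199,
                    seed = sample.int(1e6, 1))$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})
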