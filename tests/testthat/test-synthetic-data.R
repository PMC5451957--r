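test_that("scenario generation is deterministic under a fixed seed", {
  cfg <- scenario_config(n_subjects = 24, grid_shape = c(8, 9), seed = 42)
  a <- generate_use_report_scenario(cfg)
  b <- generate_use_report_scenario(cfg)
  expect_identical(a$applications, b$applications)
  expect_identical(a$residences, b$residences)
  expect_identical(a$outcome_table, b$outcome_table)
  c2 <- generate_use_report_scenario(scenario_config(n_subjects = 24,
                                                     grid_shape = c(8, 9),
                                                     seed = 43))
  expect_false(identical(a$applications, c2$applications))
})

test_that("degenerate zero inflation silences a pesticide everywhere", {
  zi <- rep(0.25, 15)
  zi[3] <- 1.0
  cfg <- scenario_config(n_subjects = 16, zero_inflation = zi,
                         grid_shape = c(8, 9), seed = 7)
  sc <- generate_use_report_scenario(cfg)
  silenced <- cfg$pesticides$pesticide[3]
  expect_false(silenced %in% sc$applications$chemical)
  expect_true(all(cfg$pesticides$pesticide[-3] %in% sc$applications$chemical))
})

test_that("scenario structure: labels, windows, and geometry invariants hold", {
  cfg <- scenario_config(n_subjects = 30, n_true_clusters = 3,
                         grid_shape = c(9, 9), seed = 5)
  sc <- generate_use_report_scenario(cfg)
  expect_setequal(unique(sc$ground_truth$true_cluster), 1:3)
  # trimesters contiguous and non-overlapping
  expect_true(all(sc$pregnancies$t2_start == sc$pregnancies$t1_end + 1))
  expect_true(all(sc$pregnancies$t3_start == sc$pregnancies$t2_end + 1))
  # 1-km buffers fully inside the grid
  side <- cfg$section_side_m
  expect_true(all(sc$residences$x_m > 1000 & sc$residences$x_m < 9 * side - 1000))
  expect_true(all(sc$residences$y_m > 1000 & sc$residences$y_m < 9 * side - 1000))
  expect_true(all(sc$applications$kg > 0))
  # a too-small grid is rejected with a buffer error
  expect_error(
    generate_use_report_scenario(scenario_config(n_subjects = 5,
                                                 grid_shape = c(1, 3), seed = 1)),
    "buffer")
})

test_that("within-class correlation propagates to exposure estimates", {
  sc <- generate_use_report_scenario(
    scenario_config(n_subjects = 500, grid_shape = c(12, 18), seed = 3))
  et <- build_exposure_table(sc)
  ops <- default_pesticides()$pesticide[default_pesticides()$class == "OP"]
  ops <- intersect(ops, et$retained)
  expect_gte(length(ops), 5)
  rho <- cor(as.matrix(et$continuous[, ops]), method = "spearman")
  mean_rho <- mean(rho[upper.tri(rho)])
  expect_gte(mean_rho, 0.6)
  expect_lte(mean_rho, 0.95)
  # marginal kg distributions right-skewed: median below mean
  cont <- as.matrix(et$continuous[, et$retained])
  expect_true(all(apply(cont, 2, median) < colMeans(cont)))
})

test_that("generated outcome variance decomposes as configured", {
  spec <- data.frame(name = c("c1", "b1"), type = c("continuous", "binary"),
                     effect = c(2, 1))
  dat <- generate_profiles_direct(20000, P = 2, K = 2,
                                  cluster_effects = c(0, -6),
                                  confounder_spec = spec,
                                  noise_sd = 3, seed = 2)
  y <- dat$outcome_table$fsiq
  # cluster var: equal halves at 0 / -6 -> 9; confounders: 4 * 1 + 1 * 0.25;
  # noise: 9
  expect_equal(var(y), 9 + 4 + 0.25 + 9, tolerance = 0.05)
})

test_that("direct profile generation honors probabilities and dimensions", {
  # degenerate: cluster 1 always category 1, cluster 2 always category K
  probs <- array(0, dim = c(2, 3, 4))
  probs[1, , 1] <- 1
  probs[2, , 4] <- 1
  dat <- generate_profiles_direct(40, P = 3, K = 4, category_probs = probs,
                                  cluster_effects = c(0, -5),
                                  confounder_spec = NULL, seed = 1)
  g <- dat$ground_truth$true_cluster
  expect_true(all(dat$profiles[g == 1, ] == 1))
  expect_true(all(dat$profiles[g == 2, ] == 4))

  # uniform probabilities: category frequencies near 1/K
  K <- 4
  unif <- array(1 / K, dim = c(1, 2, K))
  dat2 <- generate_profiles_direct(1000, P = 2, K = K, category_probs = unif,
                                   cluster_effects = 0, confounder_spec = NULL,
                                   seed = 3)
  freq <- tabulate(dat2$profiles[, 1], nbins = K) / 1000
  se <- sqrt((1 / K) * (1 - 1 / K) / 1000)
  expect_true(all(abs(freq - 1 / K) < 3 * se))

  # defaults give n x 15 with entries in 1..4
  dat3 <- generate_profiles_direct(25, seed = 4)
  expect_equal(dim(dat3$profiles), c(25, 15))
  expect_true(all(dat3$profiles %in% 1:4))

  expect_error(generate_profiles_direct(10, P = 2, K = 1, seed = 1), "K")
  bad <- array(0.3, dim = c(1, 2, 4))
  expect_error(generate_profiles_direct(10, P = 2, K = 4,
                                        category_probs = bad,
                                        cluster_effects = 0, seed = 1),
               "sum to 1")
})

test_that("scenario round-trips through CSV files", {
  sc <- generate_use_report_scenario(scenario_config(n_subjects = 10,
                                                     grid_shape = c(8, 9),
                                                     seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir, geojson = TRUE)
  expect_true(all(file.exists(paths)))
  apps <- read.csv(paths[["applications"]])
  expect_identical(nrow(apps), nrow(sc$applications))
  expect_identical(sort(names(apps)), sort(c("section_id", "date", "chemical", "kg")))
  gj <- jsonlite::read_json(paths[["geojson"]])
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(sc$sections))
})
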