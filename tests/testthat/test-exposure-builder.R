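side <- 1609.34

test_that("buffer weight handles containment, exclusion, and the centered disk", {
  poly <- unit_square(side)
  # polygon far outside the disk
  far <- poly + 10000
  expect_equal(buffer_section_weight(c(0, 0), far, 1000), 0)
  # small polygon entirely inside the disk
  small <- unit_square(10) + 200
  expect_equal(buffer_section_weight(c(205, 205), small, 1000), 1)
  # disk centered in a one-mile section: exact value vs Monte-Carlo oracle
  ctr <- c(side / 2, side / 2)
  w <- buffer_section_weight(ctr, poly, 1000)
  set.seed(1)
  m <- 2e6
  pts <- cbind(runif(m, 0, side), runif(m, 0, side))
  mc <- mean((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <= 1e6)
  expect_lt(abs(w - mc), 1e-3)
  expect_error(buffer_section_weight(c(0, 0), cbind(c(0, 1, 2), c(0, 0, 0)), 1000),
               "zero-area")
  expect_error(buffer_section_weight(c(0, 0), poly, -5), "positive")
})

test_that("buffer weight is exact on random polygon fixtures", {
  set.seed(7)
  for (rep in 1:5) {
    # random triangle near the disk boundary
    tri <- matrix(runif(6, -1500, 1500), 3, 2)
    if (abs(pestmix:::polygon_area(tri)) < 1e4) next
    w <- buffer_section_weight(c(0, 0), tri, 1000)
    pts <- cbind(runif(4e5, min(tri[, 1]), max(tri[, 1])),
                 runif(4e5, min(tri[, 2]), max(tri[, 2])))
    inside_tri <- rep(TRUE, nrow(pts))
    # barycentric point-in-triangle
    d <- function(p1, p2, p3) {
      (p1[, 1] - p3[1]) * (p2[2] - p3[2]) - (p2[1] - p3[1]) * (p1[, 2] - p3[2])
    }
    b1 <- d(pts, tri[1, ], tri[2, ]) < 0
    b2 <- d(pts, tri[2, ], tri[3, ]) < 0
    b3 <- d(pts, tri[3, ], tri[1, ]) < 0
    inside_tri <- (b1 == b2) & (b2 == b3)
    in_disk <- rowSums(pts^2) <= 1e6
    mc <- sum(inside_tri & in_disk) / sum(inside_tri)
    expect_lt(abs(w - mc), 0.01)
  }
})

make_mini_world <- function() {
  # section B two miles east: outside any 1-km buffer around A's centre
  sections <- tibble::tibble(
    section_id = c("A", "B"),
    xmin = c(0, 2 * side), xmax = c(side, 3 * side),
    ymin = c(0, 0), ymax = c(side, side))
  pregnancy <- tibble::tibble(
    subject_id = "s1",
    t1_start = as.Date("2000-01-01"), t1_end = as.Date("2000-04-02"),
    t2_start = as.Date("2000-04-03"), t2_end = as.Date("2000-07-04"),
    t3_start = as.Date("2000-07-05"), t3_end = as.Date("2000-10-06"))
  residence <- tibble::tibble(
    subject_id = "s1", x_m = side / 2, y_m = side / 2,
    start_date = as.Date("1999-12-01"), end_date = as.Date("2000-11-01"))
  list(sections = sections, pregnancy = pregnancy, residence = residence)
}

test_that("trimester use sums weighted applications within date windows", {
  w <- make_mini_world()
  wt <- buffer_section_weight(c(side / 2, side / 2),
                              unit_square(side), 1000)
  apps <- tibble::tibble(
    section_id = c("A", "A", "B"),
    date = as.Date(c("2000-02-01", "2000-05-01", "2000-02-15")),
    chemical = "diazinon", kg = c(10, 4, 100))
  tu <- trimester_use(apps, w$residence, w$pregnancy, "diazinon",
                      w$sections, radius_m = 1000)
  # section B is > 1 km away from the residence centre (weight 0)
  expect_equal(tu$kg, c(10 * wt, 4 * wt, 0))
  expect_equal(tu$days_known, c(93, 93, 94))
  # no applications of the chemical: zero estimates, same days
  tu0 <- trimester_use(apps[0, ], w$residence, w$pregnancy, "diazinon",
                       w$sections, radius_m = 1000)
  expect_equal(tu0$kg, c(0, 0, 0))
  expect_equal(tu0$days_known, c(93, 93, 94))
})

test_that("a boundary-dated application counts once, to the earlier trimester", {
  w <- make_mini_world()
  # shared boundary: make trimester 2 start on trimester 1's end date
  preg <- w$pregnancy
  preg$t2_start <- preg$t1_end
  apps <- tibble::tibble(section_id = "A", date = preg$t1_end,
                         chemical = "diazinon", kg = 10)
  tu <- trimester_use(apps, w$residence, preg, "diazinon", w$sections, 1000)
  expect_gt(tu$kg[1], 0)
  expect_equal(tu$kg[2], 0)
  expect_equal(sum(tu$kg > 0), 1)
})

test_that("overlapping residence windows are rejected as ambiguous", {
  w <- make_mini_world()
  res2 <- rbind(w$residence, w$residence)
  apps <- tibble::tibble(section_id = "A", date = as.Date("2000-02-01"),
                         chemical = "diazinon", kg = 1)
  expect_error(trimester_use(apps, res2, w$pregnancy, "diazinon",
                             w$sections, 1000),
               "overlap")
})

test_that("pregnancy averaging applies the qualifying-trimester rule", {
  expect_equal(pregnancy_average(c(10, 20, 0), c(90, 90, 10)), 15)
  expect_true(is.na(pregnancy_average(c(10, 20, 0), c(90, 10, 10))))
  expect_equal(pregnancy_average(c(3, 6, 9), c(90, 90, 90)), 6)
  expect_equal(pregnancy_average(c(5, 5, 5), c(75, 75, 10)), 5)
  expect_error(pregnancy_average(numeric(0), numeric(0)), "1-3")
})

test_that("inclusion filter keeps contrastful, used pesticides", {
  m <- cbind(
    mostly_zero = c(0, 0, 0, 0, 0, 1, 2, 3),         # median 0 -> out
    twofold = c(2, 2, 2, 3, 3, 4, 4, 4),             # q25=2, q75=4 -> in
    constant = rep(5, 8),                            # no contrast -> out
    zero_q25 = c(0, 0, 1, 2, 3, 4, 5, 6))            # q25=0, median>0 -> in
  kept <- inclusion_filter(m)
  expect_identical(as.character(kept), c("twofold", "zero_q25"))
  expect_error(inclusion_filter(m[1:3, ]), "4 subjects")
  expect_error(inclusion_filter(matrix(numeric(0), 0, 0)), "empty")
})

test_that("quartile discretization uses half-open interpolated bins", {
  expect_identical(as.integer(quartile_discretize(c(1, 2, 3, 4))), c(1L, 2L, 3L, 4L))
  expect_warning(out <- quartile_discretize(rep(2, 6)), "constant")
  expect_true(all(out == 1L))
  # invariance under strictly increasing monotone maps
  set.seed(11)
  x <- rgamma(40, 1.5)
  base <- as.integer(quartile_discretize(x))
  for (f in list(function(v) v^2, function(v) log1p(v), function(v) 3 * v + 1)) {
    expect_identical(as.integer(suppressWarnings(quartile_discretize(f(x)))), base)
  }
  # near-balanced categories without ties
  tabs <- table(base)
  expect_true(all(abs(tabs - 10) <= 1))
})

test_that("exposure table obeys mass, translation, and scaling invariances", {
  sc <- generate_use_report_scenario(scenario_config(n_subjects = 12,
                                                     grid_shape = c(8, 9),
                                                     seed = 21))
  et <- build_exposure_table(sc, apply_filter = FALSE)
  # mass bound: per-subject estimate cannot exceed total applied nearby
  chem <- sc$config$pesticides$pesticide[1]
  total <- sum(sc$applications$kg[sc$applications$chemical == chem])
  expect_true(all(et$continuous[[chem]] <= total + 1e-9))

  # translation invariance
  sc2 <- sc
  sc2$residences$x_m <- sc2$residences$x_m + 5000
  sc2$sections$xmin <- sc2$sections$xmin + 5000
  sc2$sections$xmax <- sc2$sections$xmax + 5000
  et2 <- build_exposure_table(sc2, apply_filter = FALSE)
  expect_equal(et2$continuous, et$continuous, tolerance = 1e-10)

  # kg scaling doubles estimates, leaves profiles unchanged
  sc3 <- sc
  sc3$applications$kg <- sc3$applications$kg * 2
  et3 <- build_exposure_table(sc3, apply_filter = FALSE)
  expect_equal(as.matrix(et3$continuous[, -1]),
               2 * as.matrix(et$continuous[, -1]), tolerance = 1e-10)
  expect_identical(et3$profiles, et$profiles)
})

test_that("subjects with too few located trimesters are excluded", {
  sc <- generate_use_report_scenario(scenario_config(n_subjects = 8,
                                                     grid_shape = c(8, 9),
                                                     seed = 2))
  # subject 1's residence known only during trimester 1
  sc$residences$end_date[1] <- sc$pregnancies$t1_end[1]
  sc$residences$start_date[1] <- sc$pregnancies$t1_start[1]
  et <- build_exposure_table(sc, apply_filter = FALSE)
  expect_identical(et$excluded_subjects, sc$residences$subject_id[1])
  expect_equal(nrow(et$profiles), 7)
})
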