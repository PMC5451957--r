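#' Default pesticide set and chemical classes
#'
#' Fifteen pesticides from five chemical classes (seven organophosphates,
#' two carbamates, four pyrethroids, one Mn-based fungicide, one
#' neonicotinoid), the panel retained by proximity-based inclusion screening
#' in agricultural-cohort analyses of this kind.
#'
#' @return A tibble with columns `pesticide`, `class`, and `base_meanlog`
#'   (per-application log-kg location parameter; values span the orders of
#'   magnitude seen in use-report summaries, from maneb down to
#'   cypermethrin).
#' @export
default_pesticides <- function() {
  tibble(
    pesticide = c("oxydemeton-methyl", "acephate", "chlorpyrifos", "diazinon",
                  "malathion", "dimethoate", "naled",
                  "methomyl", "thiodicarb",
                  "permethrin", "cypermethrin", "cyhalothrin", "esfenvalerate",
                  "maneb", "imidacloprid"),
    class = c(rep("OP", 7), rep("carbamate", 2), rep("pyrethroid", 4),
              "mn_fungicide", "neonicotinoid"),
    base_meanlog = c(0.5, 0.6, 0.6, 1.0, 0.3, 0.2, -0.6,
                     0.6, -1.5,
                     -0.2, -2.5, -1.9, -1.8,
                     1.6, -0.3)
  )
}

#' Scenario configuration for the synthetic use-report generator
#'
#' Defines the study conditions emulated by [generate_use_report_scenario()]:
#' a square-mile section grid, zero-inflated log-normal application amounts
#' with a shared per-section class factor (one-factor Gaussian copula)
#' driving high within-class correlation, a small number of spatially
#' contiguous latent joint-use clusters, and a cluster-structured continuous
#' outcome with confounding.
#'
#' @param n_subjects Number of subjects.
#' @param pesticides Tibble as returned by [default_pesticides()] (columns
#'   `pesticide`, `class`, `base_meanlog`).
#' @param n_true_clusters Number of planted joint-use clusters.
#' @param cluster_use_multipliers Optional `n_true_clusters` x P nonnegative
#'   matrix scaling each cluster's section-level use; default rows cycle
#'   through (low 0.2, high 5, moderately-high 2 with a pesticide-dependent
#'   tilt).
#' @param within_class_correlation Latent correlation in `[0, 1)` shared by
#'   pesticides of one chemical class within a section-period.
#' @param zero_inflation Per-pesticide probability in `[0, 1)` that a
#'   section-period has no application (recycled to length P).
#' @param amount_sdlog Log-scale sd of application amounts.
#' @param temporal_share Share of latent variance that is period-specific
#'   (the remainder is a persistent section-level intensity).
#' @param outcome_effects Per-cluster outcome shifts on the FSIQ scale.  The
#'   default preset `c(0, -6.9, -6.4)` plants the deficit scale reported for
#'   the two high-use clusters relative to the low-use reference.
#' @param outcome_intercept Baseline outcome level for the reference cluster.
#' @param confounder_spec Data frame (`name`, `type` in
#'   `c("continuous","binary")`, `effect`); see [default_confounders()].
#' @param noise_sd Residual outcome standard deviation.
#' @param grid_shape Integer c(rows, cols) of the section grid.
#' @param section_side_m Side length of one section in meters (default one
#'   mile).
#' @param buffer_radius_m Buffer radius subjects' residences must keep from
#'   the grid edge.
#' @param conception_window Length-2 Date vector for conception dates.
#' @param application_period_days Days between candidate application periods.
#' @param seed Integer seed; identical seeds give identical scenarios.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_subjects = 120,
                            pesticides = default_pesticides(),
                            n_true_clusters = 3,
                            cluster_use_multipliers = NULL,
                            within_class_correlation = 0.8,
                            zero_inflation = 0.25,
                            amount_sdlog = 1.0,
                            temporal_share = 0.2,
                            outcome_effects = c(0, -6.9, -6.4),
                            outcome_intercept = 102.5,
                            confounder_spec = default_confounders(),
                            noise_sd = 9,
                            grid_shape = c(12, 12),
                            section_side_m = 1609.34,
                            buffer_radius_m = 1000,
                            conception_window = as.Date(c("1999-10-01", "2000-09-30")),
                            application_period_days = 14,
                            seed = 1L) {
  P <- nrow(pesticides)
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_true_clusters <- check_count(n_true_clusters, "n_true_clusters")
  zero_inflation <- rep_len(zero_inflation, P)
  if (any(zero_inflation < 0 | zero_inflation > 1)) {
    abort("`zero_inflation` must lie in [0, 1]")
  }
  if (within_class_correlation < 0 || within_class_correlation >= 1) {
    abort("`within_class_correlation` must lie in [0, 1)")
  }
  if (is.null(cluster_use_multipliers)) {
    # planted joint-use patterns: one low-everything cluster, one
    # high-everything cluster, further clusters moderately high with a
    # pesticide-dependent tilt (crop-pattern-like variation)
    base <- c(0.2, 5, 2)
    cluster_use_multipliers <- matrix(
      rep(base[((seq_len(n_true_clusters) - 1) %% 3) + 1], P),
      n_true_clusters, P)
    tilt <- rep_len(c(1, 0.6, 1.5), P)
    for (g in seq_len(n_true_clusters)) {
      if (((g - 1) %% 3) + 1 == 3) {
        cluster_use_multipliers[g, ] <- cluster_use_multipliers[g, ] * tilt
      }
    }
  }
  cluster_use_multipliers <- as.matrix(cluster_use_multipliers)
  if (!all(dim(cluster_use_multipliers) == c(n_true_clusters, P)) ||
      any(cluster_use_multipliers < 0)) {
    abort("`cluster_use_multipliers` must be a nonnegative n_true_clusters x P matrix")
  }
  if (length(outcome_effects) != n_true_clusters) {
    abort("`outcome_effects` must have one entry per true cluster")
  }
  if (anyDuplicated(pesticides$pesticide)) abort("duplicate pesticide names")
  structure(list(
    n_subjects = n_subjects, pesticides = pesticides,
    n_true_clusters = n_true_clusters,
    cluster_use_multipliers = cluster_use_multipliers,
    within_class_correlation = within_class_correlation,
    zero_inflation = zero_inflation,
    amount_sdlog = amount_sdlog,
    temporal_share = temporal_share,
    outcome_effects = outcome_effects,
    outcome_intercept = outcome_intercept,
    confounder_spec = confounder_spec,
    noise_sd = noise_sd,
    grid_shape = as.integer(grid_shape),
    section_side_m = section_side_m,
    buffer_radius_m = buffer_radius_m,
    conception_window = conception_window,
    application_period_days = application_period_days,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Default confounder specification
#'
#' Ten confounders mirroring the covariate set commonly adjusted for in
#' prenatal pesticide / child-cognition analyses: home environment score,
#' household poverty, child age at assessment, sex, language of assessment,
#' maternal education, maternal verbal ability, country of birth, maternal
#' depression, and log10 urinary DAP metabolites.
#'
#' @return A data frame with columns `name`, `type`, `effect`.
#' @export
default_confounders <- function() {
  data.frame(
    name = c("home_score", "poverty", "child_age", "sex", "language",
             "maternal_education", "maternal_ppvt", "country_of_birth",
             "maternal_depression", "log10_dap"),
    type = c("continuous", "binary", "continuous", "binary", "binary",
             "binary", "continuous", "binary", "binary", "continuous"),
    effect = c(1.5, -2, 0.5, 0, -1, 2, 2.5, 1, -1.5, -1.2),
    stringsAsFactors = FALSE
  )
}

simulate_confounders <- function(spec, n) {
  if (is.null(spec) || nrow(spec) == 0) {
    return(list(W = matrix(0, n, 0), df = tibble(.rows = n), effects = numeric(0)))
  }
  cols <- lapply(seq_len(nrow(spec)), function(j) {
    if (spec$type[j] == "continuous") rnorm(n) else rbinom(n, 1, 0.5)
  })
  df <- as_tibble(setNames(cols, spec$name))
  W <- as.matrix(df)
  list(W = W, df = df, effects = setNames(spec$effect, spec$name))
}

#' Generate a synthetic use-report scenario with planted structure
#'
#' Emulates the structure of state use-report records: per-section
#' applications (section id, date, active ingredient, kilograms), maternal
#' residences with occupancy windows, pregnancy trimester windows, and an
#' outcome/confounder table, together with the ground truth needed for
#' recovery testing.
#'
#' Section-period amounts are zero-inflated log-normal: a latent Gaussian
#' with a shared per-(section, period, class) factor (one-factor copula,
#' correlation `within_class_correlation`) drives both occurrence and
#' log-amount, and is scaled by the section's latent cluster multiplier.
#' Cluster multipliers are assigned to contiguous column blocks of the grid
#' so that subjects of the same true cluster are spatially contiguous and
#' cumulative use is positively spatially autocorrelated.  The outcome is
#' the true cluster effect plus a linear confounder term plus Gaussian
#' noise.
#'
#' @param config A [scenario_config()].
#' @return A list of class `pestmix_scenario` with tibbles `applications`,
#'   `residences`, `pregnancies`, `outcome_table`, `ground_truth`,
#'   `sections` (grid geometry), and the `config`.
#' @export
generate_use_report_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  P <- nrow(config$pesticides)
  gr <- config$grid_shape[1]
  gc <- config$grid_shape[2]
  side <- config$section_side_m
  K <- config$n_true_clusters

  # grid sections; clusters occupy contiguous column blocks
  col_block <- rep(seq_len(K), each = ceiling(gc / K), length.out = gc)
  sections <- tidyr::expand_grid(row = seq_len(gr), col = seq_len(gc))
  sections$section_id <- sprintf("S%02d_%02d", sections$row, sections$col)
  sections$xmin <- (sections$col - 1) * side
  sections$xmax <- sections$col * side
  sections$ymin <- (sections$row - 1) * side
  sections$ymax <- sections$row * side
  sections$true_cluster <- col_block[sections$col]

  # subjects: cluster labels round-robin, residences inside their cluster's
  # column block, inset from the grid edge by the buffer radius
  n <- config$n_subjects
  labels <- rep(seq_len(K), length.out = n)
  inset <- config$buffer_radius_m + 1
  xr <- vapply(seq_len(K), function(g) {
    cols <- which(col_block == g)
    lo <- max((min(cols) - 1) * side, 0)
    hi <- min(max(cols) * side, gc * side)
    c(max(lo, inset), min(hi, gc * side - inset))
  }, numeric(2))
  if (any(xr[2, ] <= xr[1, ]) || inset >= gr * side - inset) {
    abort("grid too small: a residence 1-km buffer would exit the grid; enlarge `grid_shape`")
  }
  x_m <- runif(n, xr[1, labels], xr[2, labels])
  y_m <- runif(n, inset, gr * side - inset)

  conception <- config$conception_window[1] +
    floor(runif(n, 0, as.numeric(diff(config$conception_window)) + 1))
  pregnancies <- tibble(
    subject_id = sprintf("subj_%03d", seq_len(n)),
    t1_start = conception, t1_end = conception + 92,
    t2_start = conception + 93, t2_end = conception + 185,
    t3_start = conception + 186, t3_end = conception + 279
  )
  residences <- tibble(
    subject_id = pregnancies$subject_id,
    x_m = x_m, y_m = y_m,
    start_date = conception - 30,
    end_date = conception + 310
  )

  # candidate application periods must cover every pregnancy
  app_start <- min(residences$start_date) - 7
  app_end <- max(residences$end_date) + 7
  period_starts <- seq(app_start, app_end, by = config$application_period_days)

  classes <- config$pesticides$class
  class_levels <- unique(classes)
  rho <- config$within_class_correlation
  zi <- config$zero_inflation
  thr <- qnorm(pmin(zi, 1 - 1e-12))
  thr[zi >= 1] <- Inf

  ns <- nrow(sections)
  np <- length(period_starts)
  recs <- vector("list", np)
  mult <- config$cluster_use_multipliers
  # persistent section-level latents: a shared class factor (the one-factor
  # copula driving within-class correlation) plus a pesticide-specific
  # section intensity; a per-period innovation adds temporal variation that
  # averages out in pregnancy-long aggregates
  f_sec <- matrix(rnorm(ns * length(class_levels)), ns, length(class_levels),
                  dimnames = list(NULL, class_levels))
  e_sec <- matrix(rnorm(ns * P), ns, P)
  ts <- config$temporal_share
  g_persist <- sqrt(1 - ts) * (sqrt(rho) * f_sec[, classes, drop = FALSE] +
                                 sqrt(1 - rho) * e_sec)
  for (t in seq_len(np)) {
    g <- g_persist + sqrt(ts) * matrix(rnorm(ns * P), ns, P)
    occ <- sweep(g, 2, thr, ">")
    if (!any(occ)) next
    kg <- exp(sweep(g * config$amount_sdlog, 2,
                    config$pesticides$base_meanlog, "+")) *
      mult[sections$true_cluster, , drop = FALSE]
    idx <- which(occ, arr.ind = TRUE)
    recs[[t]] <- tibble(
      section_id = sections$section_id[idx[, 1]],
      date = period_starts[t] +
        floor(runif(nrow(idx), 0, config$application_period_days)),
      chemical = config$pesticides$pesticide[idx[, 2]],
      kg = kg[idx]
    )
  }
  applications <- dplyr::bind_rows(recs)
  applications <- dplyr::arrange(applications, .data$date, .data$section_id,
                                 .data$chemical)

  conf <- simulate_confounders(config$confounder_spec, n)
  y <- config$outcome_intercept + config$outcome_effects[labels] +
    (if (ncol(conf$W) > 0) as.vector(conf$W %*% conf$effects) else 0) +
    rnorm(n, 0, config$noise_sd)
  outcome_table <- dplyr::bind_cols(
    tibble(subject_id = pregnancies$subject_id, fsiq = y), conf$df)

  ground_truth <- tibble(
    subject_id = pregnancies$subject_id,
    true_cluster = labels,
    true_effect = config$outcome_effects[labels]
  )

  structure(list(
    applications = applications,
    residences = residences,
    pregnancies = pregnancies,
    outcome_table = outcome_table,
    ground_truth = ground_truth,
    true_confounder_effects = conf$effects,
    sections = sections,
    config = config
  ), class = "pestmix_scenario")
}

#' @export
print.pestmix_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic use-report scenario: %d subjects, %d pesticides, %d planted clusters\n",
    x$config$n_subjects, nrow(x$config$pesticides), x$config$n_true_clusters))
  cat(sprintf("  %d application records over %d sections\n",
              nrow(x$applications), nrow(x$sections)))
  invisible(x)
}

#' Write scenario tables to CSV (and section polygons to GeoJSON)
#'
#' @param scenario A `pestmix_scenario`.
#' @param dir Output directory (created if needed).
#' @param geojson Also write the section polygons as a GeoJSON
#'   FeatureCollection in planar coordinates?
#' @return Invisibly, the vector of paths written.
#' @export
write_scenario <- function(scenario, dir, geojson = FALSE) {
  stopifnot(inherits(scenario, "pestmix_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    applications = file.path(dir, "applications.csv"),
    residences = file.path(dir, "residences.csv"),
    pregnancies = file.path(dir, "pregnancies.csv"),
    outcome = file.path(dir, "outcome_table.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"),
    sections = file.path(dir, "sections.csv")
  )
  write.csv(scenario$applications, paths["applications"], row.names = FALSE)
  write.csv(scenario$residences, paths["residences"], row.names = FALSE)
  write.csv(scenario$pregnancies, paths["pregnancies"], row.names = FALSE)
  write.csv(scenario$outcome_table, paths["outcome"], row.names = FALSE)
  write.csv(scenario$ground_truth, paths["ground_truth"], row.names = FALSE)
  write.csv(scenario$sections, paths["sections"], row.names = FALSE)
  if (geojson) {
    gj <- file.path(dir, "sections.geojson")
    features <- lapply(seq_len(nrow(scenario$sections)), function(i) {
      s <- scenario$sections[i, ]
      list(type = "Feature",
           properties = list(section_id = s$section_id),
           geometry = list(type = "Polygon", coordinates = list(list(
             c(s$xmin, s$ymin), c(s$xmax, s$ymin), c(s$xmax, s$ymax),
             c(s$xmin, s$ymax), c(s$xmin, s$ymin)))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         gj, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, geojson = gj)
  }
  invisible(paths)
}

#' Generate categorical profiles directly at the sampler's input level
#'
#' Bypasses the GIS stage: draws each subject's quartile category from a
#' cluster-specific categorical distribution, and an outcome from the
#' planted cluster effects plus confounders plus noise.  Used for fast
#' recovery tests of the profile-regression model.
#'
#' @param n Number of subjects.
#' @param P Number of exposures (default 15).
#' @param K Categories per exposure (default 4); must be at least 2.
#' @param labels Optional integer vector of true cluster labels (default:
#'   round-robin over `nrow(category_probs)` clusters).
#' @param category_probs Array `n_clusters x P x K` of category probability
#'   simplexes (rows must sum to 1 within 1e-12); see
#'   [cluster_category_probs()].
#' @param cluster_effects Per-cluster outcome shifts (default the FSIQ-scale
#'   preset `c(0, -6.9, -6.4)`).
#' @param confounder_spec Data frame as in [default_confounders()], or
#'   `NULL` for none.
#' @param outcome_intercept,noise_sd Outcome model constants.
#' @param seed Integer seed.
#' @return A list with `profiles` (n x P integer matrix), `outcome_table`
#'   (tibble: `subject_id`, `fsiq`, confounders), and `ground_truth`.
#' @export
generate_profiles_direct <- function(n, P = 15, K = 4, labels = NULL,
                                     category_probs = NULL,
                                     cluster_effects = c(0, -6.9, -6.4),
                                     confounder_spec = default_confounders(),
                                     outcome_intercept = 102.5,
                                     noise_sd = 9,
                                     seed = 1L) {
  n <- check_count(n, "n")
  K <- check_count(K, "K", min = 2L)
  set.seed(as.integer(seed))
  if (is.null(category_probs)) {
    category_probs <- cluster_category_probs(length(cluster_effects), P, K)
  }
  G <- dim(category_probs)[1]
  if (!all(dim(category_probs)[2:3] == c(P, K))) {
    abort("`category_probs` must be n_clusters x P x K")
  }
  sums <- apply(category_probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-12)) {
    abort("each category probability vector must sum to 1 within 1e-12")
  }
  if (is.null(labels)) labels <- rep(seq_len(G), length.out = n)
  if (length(cluster_effects) != G) {
    abort("`cluster_effects` must have one entry per cluster")
  }
  x <- matrix(0L, n, P)
  for (g in seq_len(G)) {
    members <- which(labels == g)
    for (p in seq_len(P)) {
      x[members, p] <- sample.int(K, length(members), replace = TRUE,
                                  prob = category_probs[g, p, ])
    }
  }
  colnames(x) <- paste0("x", seq_len(P))
  conf <- simulate_confounders(confounder_spec, n)
  y <- outcome_intercept + cluster_effects[labels] +
    (if (ncol(conf$W) > 0) as.vector(conf$W %*% conf$effects) else 0) +
    rnorm(n, 0, noise_sd)
  list(
    profiles = x,
    outcome_table = dplyr::bind_cols(
      tibble(subject_id = sprintf("subj_%03d", seq_len(n)), fsiq = y),
      conf$df),
    ground_truth = tibble(
      subject_id = sprintf("subj_%03d", seq_len(n)),
      true_cluster = labels,
      true_effect = cluster_effects[labels]
    )
  )
}

#' FSIQ-scale recovery preset
#'
#' The named preset used by recovery tests: three planted clusters with
#' outcome effects `c(0, -6.9, -6.4)` (the deficit scale reported for
#' high-use clusters relative to a low-use reference), 15 exposures in 4
#' quartile categories with well-separated cluster category profiles, and
#' the default ten-confounder set.  The residual sd (4.5) is chosen so a
#' cluster-vs-reference mean difference at `n = 300` has a Monte Carlo
#' standard error of about 0.64, making the planted effects statistically
#' identifiable at this sample size.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param peak Category-probability mass on each cluster's target quartile.
#' @return As [generate_profiles_direct()].
#' @export
preset_fsiq_recovery <- function(n = 300, seed = 1L, peak = 0.7) {
  generate_profiles_direct(
    n = n, P = 15, K = 4,
    category_probs = cluster_category_probs(3, 15, 4, peak = peak),
    cluster_effects = c(0, -6.9, -6.4),
    confounder_spec = default_confounders(),
    outcome_intercept = 102.5, noise_sd = 4.5, seed = seed)
}

#' Separated cluster-specific category probabilities
#'
#' Builds an `n_clusters x P x K` probability array in which cluster `g`
#' concentrates mass `peak` on a target category (cluster 1 the lowest
#' category, cluster 2 the highest, further clusters interior categories),
#' with the remainder spread geometrically over the other categories.
#'
#' @param n_clusters,P,K Dimensions.
#' @param peak Probability mass on the target category.
#' @param targets Optional integer vector of per-cluster target categories.
#' @return A numeric array of simplexes.
#' @export
cluster_category_probs <- function(n_clusters, P, K, peak = 0.7,
                                   targets = NULL) {
  if (is.null(targets)) {
    targets <- c(1, K, if (n_clusters > 2) {
      pmax(2, pmin(K - 1, round(seq(K - 1, 2, length.out = n_clusters - 2))))
    })[seq_len(n_clusters)]
  }
  arr <- array(0, dim = c(n_clusters, P, K))
  for (g in seq_len(n_clusters)) {
    w <- 0.5^abs(seq_len(K) - targets[g])
    w[targets[g]] <- 0
    w <- w / sum(w) * (1 - peak)
    w[targets[g]] <- peak
    for (p in seq_len(P)) arr[g, p, ] <- w
  }
  arr
}
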