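#' Default pipeline configuration
#'
#' A nested list (one block per stage) controlling [run_pipeline()].  Every
#' default is echoed into the run manifest so no silent defaults exist.
#' The shipped defaults describe a small synthetic scenario (120 subjects)
#' with MCMC lengths sized for an end-to-end run on one CPU.
#'
#' @param n_subjects Number of subjects in the simulated scenario.
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   from it.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 120, seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = c("simulate", "build-exposure", "fit-bpr", "characterize",
               "fit-bkmr", "spatial", "report"),
    simulate = list(n_subjects = n_subjects, n_true_clusters = 3,
                    outcome_effects = c(0, -6.9, -6.4),
                    within_class_correlation = 0.8,
                    zero_inflation = 0.25,
                    grid_shape = c(12, 12)),
    exposure = list(radius_m = 1000, min_days = 75, min_trimesters = 2),
    bpr = list(n_burnin = 2000, n_sweeps = 20000, n_keep = 2000,
               truncation_level = 50, variable_selection = "continuous",
               sensitivity_without_outcome = TRUE),
    bkmr = list(n_iter = 3000, n_burnin = 1000, group_prior_prob = 0.5),
    spatial = list(scheme = "k-nearest", k = 8, n_perm = 999,
                   kde_bandwidth_m = 1500)
  ), class = c("pipeline_config", "list"))
}

#' Read and validate a pipeline configuration file
#'
#' @param path YAML file with the block structure of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) abort(sprintf("unknown config block: %s", nm))
    if (is.list(cfg[[nm]])) {
      for (sub in names(raw[[nm]])) {
        if (!sub %in% names(cfg[[nm]])) {
          abort(sprintf("unknown config field: %s.%s", nm, sub))
        }
        cfg[[nm]][[sub]] <- raw[[nm]][[sub]]
      }
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$simulate$n_subjects < 8) abort("simulate.n_subjects must be >= 8")
  if (cfg$bpr$n_sweeps < 1) abort("bpr.n_sweeps must be positive")
  if (!cfg$spatial$scheme %in% c("k-nearest", "distance-band", "rook-on-grid")) {
    abort("spatial.scheme: unknown weights scheme")
  }
  if (length(cfg$simulate$outcome_effects) != cfg$simulate$n_true_clusters) {
    abort("simulate.outcome_effects must match simulate.n_true_clusters")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes simulate -> build-exposure -> fit-bpr (with, and optionally
#' without, outcome feedback) -> characterize -> fit-bkmr -> spatial ->
#' report in dependency order, writing every stage artifact plus a
#' provenance manifest (config echo, derived per-stage seeds, artifact
#' checksums) into `outdir`.
#'
#' @param config A `pipeline_config`, or the path to a YAML config file.
#' @param outdir Output directory for run artifacts.
#' @param seed Optional master-seed override.
#' @param quiet Suppress progress messages?
#' @param figures Also render PNG figures (heat map, density surface,
#'   confounder trace plots) under `figures/`?  Figures are not part of the
#'   checksum manifest; the numeric artifacts they render are.
#' @return Invisibly, a list of in-memory stage results (`scenario`,
#'   `exposure`, `bpr`, `report_tables`, ...); artifacts are on disk in
#'   `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, seed = NULL,
                         quiet = FALSE, figures = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  seeds <- list(
    simulate = derive_seed(config$seed, 1),
    bpr = derive_seed(config$seed, 2),
    bpr_no_outcome = derive_seed(config$seed, 3),
    bkmr = derive_seed(config$seed, 4),
    spatial = derive_seed(config$seed, 5)
  )

  say("stage simulate: %d subjects", config$simulate$n_subjects)
  sc_cfg <- scenario_config(
    n_subjects = config$simulate$n_subjects,
    n_true_clusters = config$simulate$n_true_clusters,
    outcome_effects = config$simulate$outcome_effects,
    within_class_correlation = config$simulate$within_class_correlation,
    zero_inflation = config$simulate$zero_inflation,
    grid_shape = config$simulate$grid_shape,
    seed = seeds$simulate)
  scenario <- generate_use_report_scenario(sc_cfg)
  write_scenario(scenario, file.path(outdir, "scenario"))

  say("stage build-exposure")
  exposure <- build_exposure_table(
    scenario, radius_m = config$exposure$radius_m,
    min_days = config$exposure$min_days,
    min_trimesters = config$exposure$min_trimesters)
  write_exposure_table(exposure, file.path(outdir, "exposure"))
  kept <- !(scenario$outcome_table$subject_id %in% exposure$excluded_subjects)
  outcome_tbl <- scenario$outcome_table[kept, ]
  confounders <- outcome_tbl[, setdiff(names(outcome_tbl),
                                       c("subject_id", "fsiq")), drop = FALSE]

  say("stage fit-bpr: %d sweeps (+%d burn-in)",
      config$bpr$n_sweeps, config$bpr$n_burnin)
  if (!"fsiq" %in% names(scenario$outcome_table)) {
    abort("missing field outcome_table.fsiq required by stage fit-bpr")
  }
  bcfg <- bpr_config(
    n_burnin = config$bpr$n_burnin, n_sweeps = config$bpr$n_sweeps,
    n_keep = config$bpr$n_keep,
    truncation_level = config$bpr$truncation_level,
    variable_selection = config$bpr$variable_selection,
    seed = seeds$bpr)
  fit <- bpr_fit(exposure$profiles, outcome_tbl$fsiq, confounders,
                 config = bcfg)
  S <- similarity(fit)
  best <- best_partition(fit, S = S)
  ref <- select_reference_cluster(best, exposure$profiles)
  report <- cluster_outcome_posteriors(fit, best, ref)
  write.csv(as.data.frame(report), file.path(outdir, "cluster_report.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(reference_cluster = ref, best_partition = best,
         zeta_posterior_mean = colMeans(fit$draws$zeta)),
    file.path(outdir, "bpr_summary.json"), auto_unbox = TRUE, digits = NA)

  comparison <- NULL
  if (isTRUE(config$bpr$sensitivity_without_outcome)) {
    say("stage fit-bpr (sensitivity: outcome excluded)")
    bcfg2 <- bpr_config(
      n_burnin = config$bpr$n_burnin, n_sweeps = config$bpr$n_sweeps,
      n_keep = config$bpr$n_keep,
      truncation_level = config$bpr$truncation_level,
      variable_selection = config$bpr$variable_selection,
      outcome_included = FALSE, seed = seeds$bpr_no_outcome)
    fit0 <- bpr_fit(exposure$profiles, outcome = NULL, config = bcfg2)
    best0 <- best_partition(fit0)
    comparison <- compare_partitions(best, best0)
    write.csv(as.data.frame(unclass(comparison$table)),
              file.path(outdir, "partition_crosstab.csv"))
    second <- second_stage_regression(best0, outcome_tbl$fsiq, confounders,
                                      reference = select_reference_cluster(
                                        best0, exposure$profiles))
    write.csv(as.data.frame(second),
              file.path(outdir, "second_stage_regression.csv"),
              row.names = FALSE)
  }

  say("stage characterize")
  heat <- heatmap_categories(best, exposure)
  ranks <- rank_clusters_by_cumulative(best, exposure)
  write.csv(as.data.frame(heat), file.path(outdir, "heatmap_categories.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(ranks), file.path(outdir, "cluster_ranking.csv"),
            row.names = FALSE)

  say("stage fit-bkmr")
  pest <- scenario$config$pesticides
  grp_map <- setNames(pest$class, pest$pesticide)[exposure$retained]
  kcfg <- km_config(groups = grp_map,
                    group_prior_prob = config$bkmr$group_prior_prob,
                    n_iter = config$bkmr$n_iter,
                    n_burnin = config$bkmr$n_burnin,
                    seed = seeds$bkmr)
  cont <- as.matrix(exposure$continuous[, exposure$retained, drop = FALSE])
  kfit <- km_fit(cont, outcome_tbl$fsiq, confounders, kcfg)
  pips <- pip_report(kfit)
  write.csv(as.data.frame(pips$group_pips),
            file.path(outdir, "group_pips.csv"), row.names = FALSE)
  write.csv(as.data.frame(pips$conditional_pips),
            file.path(outdir, "conditional_pips.csv"), row.names = FALSE)

  say("stage spatial")
  res_kept <- scenario$residences[kept, ]
  wts <- spatial_weights(res_kept[, c("x_m", "y_m")],
                         scheme = config$spatial$scheme,
                         k = config$spatial$k)
  moran_use <- global_morans_i(exposure$cumulative, wts,
                               n_perm = config$spatial$n_perm,
                               seed = seeds$spatial)
  moran_out <- global_morans_i(outcome_tbl$fsiq, wts,
                               n_perm = config$spatial$n_perm,
                               seed = seeds$spatial + 1L)
  top_cluster <- ranks$cluster[1]
  kde <- kde_surface(res_kept[best == top_cluster, c("x_m", "y_m")],
                     bandwidth_m = config$spatial$kde_bandwidth_m)
  jsonlite::write_json(
    list(cumulative_use = as.list(moran_use), outcome = as.list(moran_out),
         weights_scheme = wts$scheme, row_standardized = wts$row_standardized),
    file.path(outdir, "moran_results.json"), auto_unbox = TRUE, digits = NA)
  kde_df <- tidyr::expand_grid(xi = seq_along(kde$x), yi = seq_along(kde$y))
  kde_df <- tibble(x = kde$x[kde_df$xi], y = kde$y[kde_df$yi],
                   density = kde$z[cbind(kde_df$xi, kde_df$yi)])
  write.csv(kde_df, file.path(outdir, "kde_surface.csv"), row.names = FALSE)

  if (figures) {
    figdir <- file.path(outdir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    try({
      ggplot2::ggsave(file.path(figdir, "heatmap.png"), autoplot(heat),
                      width = 8, height = 4, dpi = 120)
      ggplot2::ggsave(file.path(figdir, "kde_surface.png"), autoplot(kde),
                      width = 6, height = 5, dpi = 120)
      ggplot2::ggsave(file.path(figdir, "cluster_posteriors.png"),
                      autoplot(report), width = 7, height = 5, dpi = 120)
      if (ncol(fit$draws$beta) > 0) {
        ggplot2::ggsave(file.path(figdir, "bpr_traces.png"),
                        plot_bpr_traces(fit), width = 9, height = 6, dpi = 120)
      }
    }, silent = TRUE)
  }

  say("stage report")
  results <- list(scenario = scenario, exposure = exposure, fit = fit,
                  best = best, reference = ref, report = report,
                  comparison = comparison, heatmap = heat, ranking = ranks,
                  pips = pips, moran_use = moran_use, moran_out = moran_out)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pestmix")),
    master_seed = config$seed,
    derived_seeds = seeds,
    config = unclass(config),
    artifacts = manifest_checksums(outdir)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report(results), file.path(outdir, "report.txt"))
  invisible(results)
}

manifest_checksums <- function(outdir) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("manifest.json", "report.txt")))
  files <- files[!startsWith(files, "figures/")]
  sums <- tools::md5sum(file.path(outdir, files))
  setNames(as.list(unname(sums)), files)
}

render_report <- function(res) {
  lines <- c("Pesticide-profile mixture analysis report",
             strrep("=", 42), "")
  rep_df <- as.data.frame(res$report)
  rep_df$difference_fmt <- ifelse(
    rep_df$reference, "Ref",
    sprintf("%.1f (%.1f, %.1f)", rep_df$difference, rep_df$difference_lo,
            rep_df$difference_hi))
  lines <- c(lines, "Cluster-level adjusted outcome (vs reference cluster):",
             utils::capture.output(print(
               rep_df[, c("cluster", "n", "adjusted_mean", "difference_fmt",
                          "deficit_probability")], row.names = FALSE)), "")
  lines <- c(lines, "Cluster ranking by cumulative use (median kg, IQR):",
             utils::capture.output(print(as.data.frame(res$ranking),
                                         row.names = FALSE)), "")
  heat_wide <- tidyr::pivot_wider(res$heatmap[, c("cluster", "pesticide", "quartile")],
                                  names_from = "pesticide",
                                  values_from = "quartile")
  lines <- c(lines, "Heat-map quartile categories (1 = very low ... 4 = very high):",
             utils::capture.output(print(as.data.frame(heat_wide),
                                         row.names = FALSE)), "")
  if (!is.null(res$comparison)) {
    lines <- c(lines,
               sprintf("Partition cross-tabulation, outcome included vs excluded (ARI = %.3f):",
                       res$comparison$ari),
               utils::capture.output(print(res$comparison$table)), "")
  }
  lines <- c(lines, "Group posterior inclusion probabilities:",
             utils::capture.output(print(as.data.frame(res$pips$group_pips),
                                         row.names = FALSE)), "")
  lines <- c(lines, sprintf(
    "Global Moran's I, cumulative use: I = %.3f (p = %.4g); outcome: I = %.3f (p = %.4g)",
    res$moran_use$I, res$moran_use$p_value,
    res$moran_out$I, res$moran_out$p_value))
  lines
}

#' Render the human-readable summary for a completed run directory
#'
#' Re-reads stage artifacts from disk and reproduces the `report.txt`
#' sections that are available, listing any missing artifacts.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return Character vector of report lines (invisibly); also printed.
#' @export
pipeline_report <- function(run_dir) {
  lines <- c("Pesticide-profile mixture analysis report",
             strrep("=", 42), "")
  want <- c("cluster_report.csv", "cluster_ranking.csv", "group_pips.csv",
            "moran_results.json")
  missing <- want[!file.exists(file.path(run_dir, want))]
  cr <- file.path(run_dir, "cluster_report.csv")
  if (file.exists(cr)) {
    df <- read.csv(cr)
    df$difference_fmt <- ifelse(df$reference, "Ref",
                                sprintf("%.1f (%.1f, %.1f)", df$difference,
                                        df$difference_lo, df$difference_hi))
    lines <- c(lines, "Cluster-level adjusted outcome (vs reference cluster):",
               utils::capture.output(print(
                 df[, c("cluster", "n", "adjusted_mean", "difference_fmt",
                        "deficit_probability")], row.names = FALSE)), "")
  }
  rk <- file.path(run_dir, "cluster_ranking.csv")
  if (file.exists(rk)) {
    lines <- c(lines, "Cluster ranking by cumulative use:",
               utils::capture.output(print(read.csv(rk), row.names = FALSE)), "")
  }
  gp <- file.path(run_dir, "group_pips.csv")
  if (file.exists(gp)) {
    lines <- c(lines, "Group posterior inclusion probabilities:",
               utils::capture.output(print(read.csv(gp), row.names = FALSE)), "")
  }
  mr <- file.path(run_dir, "moran_results.json")
  if (file.exists(mr)) {
    m <- jsonlite::read_json(mr)
    lines <- c(lines, sprintf(
      "Global Moran's I, cumulative use: I = %.3f (p = %.4g); outcome: I = %.3f (p = %.4g)",
      m$cumulative_use$I, m$cumulative_use$p_value,
      m$outcome$I, m$outcome$p_value))
  }
  if (length(missing)) {
    lines <- c(lines, "", paste("Missing artifacts:",
                                paste(missing, collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
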