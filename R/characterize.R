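heatmap_levels <- c("very low", "moderately low", "moderately high", "very high")

#' Heat-map quartile categories per cluster and pesticide
#'
#' For each best-partition cluster and each pesticide, the label is the
#' population quartile bin containing the within-cluster median of the
#' continuous use estimate ("very low" = first quartile ... "very high" =
#' fourth quartile).  A `cumulative` column is computed identically on the
#' per-subject row sums.  Even-sized clusters use the lower median so the
#' label is always an observed value's bin.
#'
#' @param best Integer partition vector.
#' @param exposure An `exposure_table` (or a numeric matrix of continuous
#'   estimates, in which case cut points are computed from it).
#' @return A tibble, one row per (cluster, pesticide) plus the cumulative
#'   column, with `cluster`, `pesticide`, `quartile` (1-4), `label`.
#' @export
heatmap_categories <- function(best, exposure) {
  if (inherits(exposure, "exposure_table")) {
    cont <- as.matrix(exposure$continuous[, exposure$retained, drop = FALSE])
    cum <- exposure$cumulative
    cuts <- exposure$cuts
  } else {
    cont <- as.matrix(exposure)
    cum <- rowSums(cont)
    cuts <- lapply(seq_len(ncol(cont)), function(j) quartile_cuts(cont[, j]))
    names(cuts) <- colnames(cont) %||% paste0("x", seq_len(ncol(cont)))
    colnames(cont) <- names(cuts)
  }
  if (length(best) != nrow(cont)) abort("partition must cover all subjects")
  ids <- sort(unique(best))
  if (any(table(factor(best, levels = ids)) == 0)) abort("empty cluster")
  cum_cuts <- quartile_cuts(cum)
  rows <- list()
  for (cl in ids) {
    members <- best == cl
    for (j in seq_len(ncol(cont))) {
      med <- lower_median(cont[members, j])
      q <- bin_by_cuts(med, cuts[[colnames(cont)[j]]])
      rows[[length(rows) + 1]] <- tibble(
        cluster = cl, pesticide = colnames(cont)[j],
        quartile = q, label = heatmap_levels[q])
    }
    qc <- bin_by_cuts(lower_median(cum[members]), cum_cuts)
    rows[[length(rows) + 1]] <- tibble(
      cluster = cl, pesticide = "cumulative",
      quartile = qc, label = heatmap_levels[qc])
  }
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = heatmap_levels)
  structure(out, class = c("heatmap_categories", class(out)))
}

#' Heat-map plot of cluster quartile categories
#'
#' Rows are clusters, columns pesticides plus the cumulative column, with a
#' four-level fill from white ("very low") to dark red ("very high").
#'
#' @param object A tibble from [heatmap_categories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot heatmap_categories
#' @export
autoplot.heatmap_categories <- function(object, ...) {
  pl <- unique(object$pesticide)
  object$pesticide <- factor(object$pesticide,
                             levels = c(setdiff(pl, "cumulative"), "cumulative"))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pesticide,
                               y = factor(.data$cluster),
                               fill = .data$label)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(
      values = c("very low" = "white", "moderately low" = "#fcae91",
                 "moderately high" = "#fb6a4a", "very high" = "#a50f15"),
      drop = FALSE) +
    ggplot2::labs(x = NULL, y = "cluster", fill = "use level") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Rank clusters by cumulative pesticide use
#'
#' Orders clusters by descending within-cluster median of the per-subject
#' cumulative (summed) use, reporting median and IQR per cluster; ties
#' break by cluster id.
#'
#' @param best Integer partition vector.
#' @param exposure An `exposure_table` or numeric matrix of continuous
#'   estimates.
#' @return A tibble with columns `rank`, `cluster`, `n`, `median_kg`,
#'   `q25_kg`, `q75_kg`.
#' @export
rank_clusters_by_cumulative <- function(best, exposure) {
  cum <- if (inherits(exposure, "exposure_table")) exposure$cumulative else {
    rowSums(as.matrix(exposure))
  }
  if (length(best) != length(cum)) abort("partition must cover all subjects")
  ids <- sort(unique(best))
  tab <- tibble(
    cluster = ids,
    n = as.integer(table(factor(best, levels = ids))),
    median_kg = vapply(ids, function(cl) median(cum[best == cl]), numeric(1)),
    q25_kg = vapply(ids, function(cl) {
      quantile(cum[best == cl], 0.25, type = 7, names = FALSE)
    }, numeric(1)),
    q75_kg = vapply(ids, function(cl) {
      quantile(cum[best == cl], 0.75, type = 7, names = FALSE)
    }, numeric(1))
  )
  tab <- tab[order(-tab$median_kg, tab$cluster), ]
  tab$rank <- seq_len(nrow(tab))
  tab[, c("rank", "cluster", "n", "median_kg", "q25_kg", "q75_kg")]
}

#' Second-stage linear regression of the outcome on cluster membership
#'
#' The two-stage route used when the outcome is excluded from clustering:
#' ordinary least squares of the outcome on cluster indicators (relative to
#' the reference cluster) plus confounders, with normal-theory 95%
#' confidence intervals.
#'
#' @param best Integer partition vector.
#' @param outcome Numeric outcome vector.
#' @param confounders Optional data frame of confounders.
#' @param reference Reference cluster id.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high` for
#'   each non-reference cluster and confounder; the underlying `lm` fit is
#'   attached as attribute `fit`.
#' @export
second_stage_regression <- function(best, outcome, confounders = NULL,
                                    reference = NULL) {
  if (length(best) != length(outcome)) abort("lengths differ")
  ids <- sort(unique(best))
  if (is.null(reference)) reference <- ids[1]
  if (!reference %in% ids) abort("`reference` is not a cluster id")
  cl <- stats::relevel(factor(best, levels = ids), ref = as.character(reference))
  df <- data.frame(.y = outcome, .cluster = cl)
  if (!is.null(confounders)) df <- cbind(df, as.data.frame(confounders))
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("singular design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  ci <- suppressWarnings(confint(fit, level = 0.95))
  est <- coef(fit)
  out <- tibble(term = names(est), estimate = unname(est),
                conf.low = ci[, 1], conf.high = ci[, 2])
  out$term <- sub("^\\.cluster", "cluster_", out$term)
  # exact fits have zero residual variance and NaN intervals; report
  # zero-width intervals at the estimate
  zerovar <- !is.finite(out$conf.low)
  out$conf.low[zerovar] <- out$estimate[zerovar]
  out$conf.high[zerovar] <- out$estimate[zerovar]
  attr(out, "fit") <- fit
  attr(out, "reference") <- reference
  out
}
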