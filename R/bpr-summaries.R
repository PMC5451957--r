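#' Posterior co-clustering (similarity) matrix
#'
#' `S[i, j]` is the fraction of retained MCMC draws in which subjects `i`
#' and `j` share a mixture component.  It is invariant to cluster
#' relabeling by construction; `1 - S` is the dissimilarity used to extract
#' a representative "best" partition.
#'
#' @param fit A `bpr_fit` object.
#' @return An n x n symmetric numeric matrix with unit diagonal.
#' @export
similarity <- function(fit) {
  stopifnot(inherits(fit, "bpr_fit"))
  if (nrow(fit$draws$z) < 1) abort("no retained draws")
  coclustering_cpp(fit$draws$z)
}

# Relabel a partition vector to consecutive ids in order of first appearance.
canonical_partition <- function(z) {
  as.integer(match(z, unique(z)))
}

#' Representative "best" partition from the co-clustering matrix
#'
#' The default (`"least-squares-draw"`) selects, among the sampled
#' partitions, the one minimizing the least-squares distance to the
#' posterior co-clustering matrix,
#' \eqn{\sum_{i<j} (1[z_i = z_j] - S_{ij})^2}.  The `"medoids"` method runs
#' partitioning-around-medoids on `1 - S` over a range of cluster counts and
#' returns the candidate minimizing the same criterion.
#'
#' @param fit A `bpr_fit` object.
#' @param S Optional precomputed similarity matrix (computed if missing).
#' @param method `"least-squares-draw"` (default) or `"medoids"`.
#' @param k_range Candidate cluster counts for the medoids method.
#' @return Integer vector of cluster labels (consecutive ids in order of
#'   first appearance), with attributes `criterion` (the achieved
#'   least-squares score) and `method`.
#' @export
best_partition <- function(fit, S = NULL,
                           method = c("least-squares-draw", "medoids"),
                           k_range = 1:10) {
  stopifnot(inherits(fit, "bpr_fit"))
  method <- match.arg(method)
  if (is.null(S)) S <- similarity(fit)
  if (method == "least-squares-draw") {
    scores <- partition_scores_cpp(fit$draws$z, S)
    best <- which.min(scores)
    z <- canonical_partition(fit$draws$z[best, ])
    attr(z, "criterion") <- scores[[best]]
  } else {
    n <- nrow(S)
    D <- 1 - S
    cand <- lapply(k_range[k_range <= n], function(k) {
      pam_partition(D, k)
    })
    scores <- vapply(cand, function(z) partition_ls_score(z, S), numeric(1))
    best <- which.min(scores)
    z <- canonical_partition(cand[[best]])
    attr(z, "criterion") <- scores[[best]]
  }
  attr(z, "method") <- method
  z
}

# Least-squares score of one partition against S (R reference used by the
# medoids route; the draw route scores in C++).
partition_ls_score <- function(z, S) {
  A <- outer(z, z, "==") * 1
  sum((A[upper.tri(A)] - S[upper.tri(S)])^2)
}

# Small deterministic PAM on a precomputed dissimilarity matrix:
# BUILD greedy initialization followed by medoid swaps until no improvement.
pam_partition <- function(D, k) {
  n <- nrow(D)
  if (k >= n) return(seq_len(n))
  medoids <- integer(0)
  for (m in seq_len(k)) {
    costs <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(Inf)
      sum(do.call(pmin, c(list(D[, j]), lapply(medoids, function(mm) D[, mm]))))
    }, numeric(1))
    medoids <- c(medoids, which.min(costs))
  }
  repeat {
    assign_cost <- function(meds) sum(apply(D[, meds, drop = FALSE], 1, min))
    current <- assign_cost(medoids)
    improved <- FALSE
    for (mi in seq_along(medoids)) {
      for (j in setdiff(seq_len(n), medoids)) {
        trial <- medoids
        trial[mi] <- j
        if (assign_cost(trial) < current - 1e-12) {
          medoids <- trial
          current <- assign_cost(medoids)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  apply(D[, medoids, drop = FALSE], 1, which.min)
}

#' Select the low-exposure reference cluster
#'
#' The reference is the cluster with the highest mean proportion of
#' observations in the lowest exposure quartile across all pesticides; ties
#' break deterministically to the smallest cluster id.
#'
#' @param best Integer partition vector.
#' @param profiles Categorical profile matrix (categories 1..K).
#' @return The reference cluster id (integer scalar) with attribute
#'   `lowest_quartile_share`, the per-cluster shares.
#' @export
select_reference_cluster <- function(best, profiles) {
  x <- as.matrix(profiles)
  if (length(best) != nrow(x)) abort("partition length must match profiles")
  ids <- sort(unique(best))
  share <- vapply(ids, function(cl) mean(x[best == cl, , drop = FALSE] == 1L),
                  numeric(1))
  ref <- ids[which.max(share)]  # which.max takes the first (smallest id) tie
  attr(ref, "lowest_quartile_share") <- setNames(share, ids)
  ref
}

#' Cluster-level posterior summaries of the adjusted outcome
#'
#' For each retained sweep and each best-partition cluster, the adjusted
#' expected outcome is the mean over the cluster's members of their sweep-
#' specific component mean (confounders held at baseline: discrete at the
#' reference level, centered continuous at zero).  Reported per cluster:
#' posterior mean and central 95% interval, the difference versus the
#' reference cluster, and the deficit probability (fraction of sweeps below
#' the reference).  An overall baseline, the unweighted across-cluster mean
#' per sweep, is attached as an attribute.
#'
#' @param fit A `bpr_fit` with outcome included.
#' @param best Integer partition vector from [best_partition()].
#' @param reference Reference cluster id (see [select_reference_cluster()]).
#' @return A `cluster_report`: a tibble with one row per cluster and columns
#'   `cluster`, `n`, `adjusted_mean`, `adjusted_lo`, `adjusted_hi`,
#'   `difference`, `difference_lo`, `difference_hi`, `deficit_probability`,
#'   `reference`; draw-level matrices are attached as attributes
#'   `value_draws` and `difference_draws`.
#' @export
cluster_outcome_posteriors <- function(fit, best, reference) {
  stopifnot(inherits(fit, "bpr_fit"))
  if (!fit$has_outcome) abort("outcome was not included in the fit")
  ids <- sort(unique(best))
  if (!reference %in% ids) abort("`reference` is not a cluster of the best partition")
  zd <- fit$draws$z
  th <- fit$draws$theta
  Tn <- nrow(zd)
  vals <- matrix(NA_real_, Tn, length(ids),
                 dimnames = list(NULL, paste0("cluster_", ids)))
  for (ci in seq_along(ids)) {
    members <- which(best == ids[ci])
    # theta_{z_i^(t)}^(t) averaged over members i of the best cluster
    idx <- zd[, members, drop = FALSE]
    thv <- matrix(th[cbind(rep(seq_len(Tn), times = length(members)),
                           as.vector(idx))], Tn, length(members))
    vals[, ci] <- rowMeans(thv)
  }
  ref_col <- match(reference, ids)
  diffs <- vals - vals[, ref_col]
  qs <- function(m) apply(m, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  vq <- qs(vals)
  dq <- qs(diffs)
  rep_tbl <- tibble(
    cluster = ids,
    n = as.integer(table(factor(best, levels = ids))),
    adjusted_mean = unname(colMeans(vals)),
    adjusted_lo = unname(vq[1, ]),
    adjusted_hi = unname(vq[2, ]),
    difference = unname(colMeans(diffs)),
    difference_lo = unname(dq[1, ]),
    difference_hi = unname(dq[2, ]),
    deficit_probability = unname(colMeans(diffs < 0)),
    reference = ids == reference
  )
  rep_tbl$difference[rep_tbl$reference] <- 0
  rep_tbl$deficit_probability[rep_tbl$reference] <- NA_real_
  structure(rep_tbl,
            class = c("cluster_report", class(rep_tbl)),
            value_draws = vals,
            difference_draws = diffs,
            overall_baseline = rowMeans(vals),
            reference = reference)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster-level adjusted outcome posteriors (reference cluster:",
      attr(x, "reference"), ")\n")
  df <- as.data.frame(x)
  df$difference <- ifelse(df$reference, "Ref",
                          sprintf("%.1f (%.1f, %.1f)", df$difference,
                                  df$difference_lo, df$difference_hi))
  df$adjusted <- sprintf("%.1f (%.1f, %.1f)", df$adjusted_mean,
                         df$adjusted_lo, df$adjusted_hi)
  print(df[, c("cluster", "n", "adjusted", "difference", "deficit_probability")],
        row.names = FALSE)
  invisible(x)
}

#' Posterior density plot of cluster-level adjusted outcomes
#'
#' @param object A `cluster_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_report
#' @export
autoplot.cluster_report <- function(object, ...) {
  vals <- attr(object, "value_draws")
  long <- tidyr::pivot_longer(as_tibble(vals), dplyr::everything(),
                              names_to = "cluster", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, colour = .data$cluster)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "adjusted expected outcome",
                  y = "cumulative posterior probability")
}

#' Compare two partitions of the same subjects
#'
#' Cross-tabulates two hard partitions (e.g., the best clusterings with and
#' without outcome feedback) and computes the Adjusted Rand Index.
#'
#' @param a,b Integer partition vectors over the same subjects.
#' @return A list of class `partition_comparison` with `table` (contingency
#'   table with row/column totals) and `ari`.
#' @export
compare_partitions <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must cover the same subjects")
  tab <- table(a = a, b = b)
  structure(list(
    table = stats::addmargins(tab),
    core_table = tab,
    ari = adjusted_rand_index(a, b),
    n = length(a)
  ), class = "partition_comparison")
}

# Chance-corrected partition agreement from the pair-counting contingency
# table (Hubert-Arabie form).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("Partition comparison over %d subjects (ARI = %.3f)\n", x$n, x$ari))
  print(x$table)
  invisible(x)
}
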