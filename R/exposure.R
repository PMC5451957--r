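#' Area-weight of a section inside a residence buffer
#'
#' Fraction of a section polygon's land area lying within a circular buffer
#' around a residence: `area(polygon intersect disk) / area(polygon)`.  The
#' intersection area is computed exactly by summing, over polygon edges,
#' triangle contributions for sub-segments inside the disk and circular-
#' sector contributions for sub-segments outside (Green's theorem applied
#' to the clipped boundary).
#'
#' @param residence Numeric length-2 point `c(x, y)` in planar meters.
#' @param polygon Numeric matrix (vertices x 2), a simple closed ring (the
#'   closing vertex may be present or omitted).
#' @param radius_m Buffer radius in meters (> 0).
#' @return Weight in `[0, 1]`.
#' @export
buffer_section_weight <- function(residence, polygon, radius_m) {
  if (!is.numeric(radius_m) || length(radius_m) != 1 || radius_m <= 0) {
    abort("`radius_m` must be a single positive number")
  }
  poly <- as.matrix(polygon)
  if (!all(is.finite(poly)) || !all(is.finite(residence))) {
    abort("coordinates must be finite")
  }
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3) abort("polygon needs at least 3 distinct vertices")
  area <- polygon_area(poly)
  if (abs(area) < 1e-12) abort("zero-area polygon")
  inter <- circle_polygon_area(residence, radius_m, poly)
  min(max(inter / abs(area), 0), 1)
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

# Exact area of polygon-disk intersection; polygon an open ring matrix.
circle_polygon_area <- function(center, radius, poly) {
  v <- sweep(poly, 2, as.numeric(center))
  if (polygon_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  n <- nrow(v)
  total <- 0
  for (e in seq_len(n)) {
    a <- v[e, ]
    b <- v[if (e == n) 1 else e + 1, ]
    total <- total + edge_circle_contrib(a, b, radius)
  }
  max(total, 0)
}

edge_circle_contrib <- function(a, b, r) {
  d <- b - a
  A <- sum(d * d)
  ts <- c(0, 1)
  if (A > 0) {
    B <- 2 * sum(a * d)
    C <- sum(a * a) - r * r
    disc <- B * B - 4 * A * C
    if (disc > 0) {
      rt <- sqrt(disc)
      for (t in c((-B - rt) / (2 * A), (-B + rt) / (2 * A))) {
        if (t > 0 && t < 1) ts <- c(ts, t)
      }
    }
  }
  ts <- sort(unique(ts))
  contrib <- 0
  for (s in seq_len(length(ts) - 1)) {
    p1 <- a + ts[s] * d
    p2 <- a + ts[s + 1] * d
    m <- (p1 + p2) / 2
    cross <- p1[1] * p2[2] - p2[1] * p1[2]
    if (sum(m * m) <= r * r) {
      contrib <- contrib + 0.5 * cross          # chord (triangle from center)
    } else {
      ang <- atan2(cross, sum(p1 * p2))         # signed angle, (-pi, pi)
      contrib <- contrib + 0.5 * r * r * ang    # circular sector
    }
  }
  contrib
}

section_ring <- function(s) {
  cbind(c(s$xmin, s$xmax, s$xmax, s$xmin),
        c(s$ymin, s$ymin, s$ymax, s$ymax))
}

# Sections whose rectangle comes within `radius` of the point.
candidate_sections <- function(x, y, sections, radius) {
  dx <- pmax(sections$xmin - x, 0, x - sections$xmax)
  dy <- pmax(sections$ymin - y, 0, y - sections$ymax)
  which(dx * dx + dy * dy <= radius * radius)
}

#' Per-trimester use estimate for one subject and one chemical
#'
#' For each trimester, sums `kg * buffer weight` over applications of the
#' chemical dated inside the intersection of the trimester with an occupancy
#' window (dates are closed intervals; an application on a shared boundary
#' date counts once, to the earlier interval), and counts the occupancy days
#' known within the trimester.
#'
#' @param applications Tibble of application records (`section_id`, `date`,
#'   `chemical`, `kg`).
#' @param residence_windows Tibble of this subject's residence windows
#'   (`x_m`, `y_m`, `start_date`, `end_date`); overlapping windows are an
#'   error (ambiguous location).
#' @param pregnancy One-row tibble with `t1_start`..`t3_end` dates.
#' @param chemical Chemical name.
#' @param sections Section geometry tibble (`section_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`).
#' @param radius_m Buffer radius in meters.
#' @return A tibble with columns `trimester`, `kg`, `days_known`.
#' @export
trimester_use <- function(applications, residence_windows, pregnancy,
                          chemical, sections, radius_m = 1000) {
  apps <- applications[applications$chemical == chemical, , drop = FALSE]
  est <- subject_exposure(apps, residence_windows, pregnancy, sections,
                          radius_m)
  bt <- est$by_trimester
  tibble(trimester = 1:3,
         kg = vapply(1:3, function(t) {
           s <- bt$kg[bt$trimester == t]
           if (length(s)) sum(s) else 0
         }, numeric(1)),
         days_known = est$days_known)
}

# Core per-subject aggregation over all chemicals at once.
subject_exposure <- function(applications, residence_windows, pregnancy,
                             sections, radius_m) {
  rw <- residence_windows[order(residence_windows$start_date), , drop = FALSE]
  if (nrow(rw) > 1) {
    for (i in 2:nrow(rw)) {
      if (rw$start_date[i] <= rw$end_date[i - 1]) {
        abort(sprintf("overlapping residence windows for subject %s (ambiguous location)",
                      rw$subject_id[1] %||% "?"))
      }
    }
  }
  tri <- matrix(c(pregnancy$t1_start, pregnancy$t1_end,
                  pregnancy$t2_start, pregnancy$t2_end,
                  pregnancy$t3_start, pregnancy$t3_end), 3, 2, byrow = TRUE)
  days_known <- numeric(3)
  pieces <- list()
  for (w in seq_len(nrow(rw))) {
    cand <- candidate_sections(rw$x_m[w], rw$y_m[w], sections, radius_m)
    wts <- vapply(cand, function(ci) {
      buffer_section_weight(c(rw$x_m[w], rw$y_m[w]),
                            section_ring(sections[ci, ]), radius_m)
    }, numeric(1))
    keep <- wts > 0
    cand <- cand[keep]
    wts <- wts[keep]
    sec_ids <- sections$section_id[cand]
    apps <- applications[applications$section_id %in% sec_ids, , drop = FALSE]
    if (nrow(apps) > 0) {
      apps$weight <- wts[match(apps$section_id, sec_ids)]
    }
    for (t in 1:3) {
      lo <- max(tri[t, 1], rw$start_date[w])
      hi <- min(tri[t, 2], rw$end_date[w])
      if (lo > hi) next
      days_known[t] <- days_known[t] + as.numeric(hi - lo) + 1
      if (nrow(apps) == 0) next
      # earlier-interval convention: a date on a boundary shared with the
      # previous trimester has already been counted there
      sel <- apps$date >= lo & apps$date <= hi
      if (t > 1) sel <- sel & apps$date > tri[t - 1, 2]
      if (any(sel)) {
        sub <- apps[sel, ]
        agg <- dplyr::summarise(dplyr::group_by(sub, .data$chemical),
                                kg = sum(.data$kg * .data$weight),
                                .groups = "drop")
        agg$trimester <- t
        pieces[[length(pieces) + 1]] <- agg
      }
    }
  }
  by_tri <- if (length(pieces)) dplyr::bind_rows(pieces) else {
    tibble(chemical = character(0), kg = numeric(0), trimester = integer(0))
  }
  by_tri <- dplyr::summarise(dplyr::group_by(by_tri, .data$chemical, .data$trimester),
                             kg = sum(.data$kg), .groups = "drop")
  list(by_trimester = by_tri, days_known = days_known)
}

#' Pregnancy-average use from per-trimester estimates
#'
#' Trimesters with at least `min_days` of known residential occupancy
#' qualify; with fewer than `min_trimesters` qualifying trimesters the
#' subject's estimate is insufficient (`NA`).  Otherwise the qualifying
#' trimester amounts are summed and divided by the number of qualifying
#' trimesters.
#'
#' @param kg Numeric vector of per-trimester kg estimates (1-3 entries).
#' @param days_known Matching vector of known occupancy days.
#' @param min_days Minimum known days for a trimester to qualify.
#' @param min_trimesters Minimum number of qualifying trimesters.
#' @return The pregnancy-average kg, or `NA_real_` when insufficient.
#' @export
pregnancy_average <- function(kg, days_known, min_days = 75,
                              min_trimesters = 2) {
  if (length(kg) < 1 || length(kg) > 3 || length(kg) != length(days_known)) {
    abort("expected 1-3 matched trimester entries")
  }
  ok <- days_known >= min_days
  if (sum(ok) < min_trimesters) return(NA_real_)
  sum(kg[ok]) / sum(ok)
}

#' Pesticide inclusion filter
#'
#' Retains a pesticide when its population median estimate is above zero
#' and there is at least a two-fold difference between the 25th and 75th
#' percentiles (inclusive: `q75 >= 2 * q25`; a zero `q25` with positive
#' median counts as infinite contrast and is retained).
#'
#' @param exposure_matrix Numeric matrix/data frame, subjects x pesticides.
#' @return Character vector of retained pesticide names, in input order,
#'   with attribute `report`, a tibble of the per-pesticide decisions.
#' @export
inclusion_filter <- function(exposure_matrix) {
  m <- as.matrix(exposure_matrix)
  if (length(m) == 0) abort("empty exposure matrix")
  if (nrow(m) < 4) abort("inclusion filter needs at least 4 subjects")
  nms <- colnames(m) %||% paste0("x", seq_len(ncol(m)))
  rep_tbl <- tibble(
    pesticide = nms,
    median = apply(m, 2, function(x) quantile(x, 0.5, type = 7, names = FALSE)),
    q25 = apply(m, 2, function(x) quantile(x, 0.25, type = 7, names = FALSE)),
    q75 = apply(m, 2, function(x) quantile(x, 0.75, type = 7, names = FALSE))
  )
  rep_tbl$retained <- rep_tbl$median > 0 &
    (rep_tbl$q25 == 0 | rep_tbl$q75 >= 2 * rep_tbl$q25)
  out <- nms[rep_tbl$retained]
  attr(out, "report") <- rep_tbl
  out
}

#' Quartile discretization of a use-estimate column
#'
#' Cut points are the empirical 25/50/75 percentiles (linear-interpolation
#' definition); categories are assigned by half-open bins
#' `(-Inf, q25], (q25, q50], (q50, q75], (q75, Inf)`.  Duplicated cut points
#' (tied mass) collapse categories deterministically toward the lower
#' category.
#'
#' @param column Numeric vector of nonnegative use estimates.
#' @return Integer categories in 1..4 with attribute `cuts` (the three cut
#'   points).
#' @export
quartile_discretize <- function(column) {
  x <- as.numeric(column)
  if (any(!is.finite(x))) abort("non-finite values in column")
  cuts <- quartile_cuts(x)
  if (length(unique(x)) == 1) {
    warn("constant column: all observations fall in category 1")
  }
  structure(bin_by_cuts(x, cuts), cuts = cuts)
}

#' Build the subject-by-pesticide exposure table
#'
#' Converts application records plus residences into per-subject
#' pregnancy-average use estimates for every chemical, applies the
#' inclusion filter, computes cumulative (summed) use over retained
#' pesticides, and discretizes each retained column into quartile profiles.
#'
#' @param applications,residences,pregnancies,sections Tibbles in the
#'   schemas written by [write_scenario()] (a `pestmix_scenario` may be
#'   passed as the single first argument instead).
#' @param radius_m Buffer radius in meters.
#' @param min_days,min_trimesters Sufficiency rule for pregnancy averaging.
#' @param apply_filter Apply the inclusion filter (`TRUE`) or retain all
#'   chemicals?
#' @return An object of class `exposure_table`: list with `continuous`
#'   (tibble `subject_id` + retained pesticide columns + `cumulative`),
#'   `profiles` (integer matrix of quartile categories), `cuts` (per-column
#'   cut points), `retained`, `excluded_subjects`, `filter_report`.
#' @export
build_exposure_table <- function(applications, residences = NULL,
                                 pregnancies = NULL, sections = NULL,
                                 radius_m = 1000, min_days = 75,
                                 min_trimesters = 2, apply_filter = TRUE) {
  if (inherits(applications, "pestmix_scenario")) {
    sc <- applications
    applications <- sc$applications
    residences <- residences %||% sc$residences
    pregnancies <- pregnancies %||% sc$pregnancies
    sections <- sections %||% sc$sections
  }
  applications$date <- as_date_safe(applications$date, "applications")
  if (any(applications$kg < 0)) abort("negative kg in application records")
  for (cc in c("start_date", "end_date")) {
    residences[[cc]] <- as_date_safe(residences[[cc]], "residences")
  }
  if (any(residences$start_date > residences$end_date)) {
    abort("residence window with start after end")
  }
  chems <- sort(unique(applications$chemical))
  subjects <- pregnancies$subject_id
  est <- matrix(NA_real_, length(subjects), length(chems),
                dimnames = list(subjects, chems))
  insufficient <- character(0)
  for (si in seq_along(subjects)) {
    sid <- subjects[si]
    rw <- residences[residences$subject_id == sid, , drop = FALSE]
    preg <- pregnancies[si, , drop = FALSE]
    se <- subject_exposure(applications, rw, preg, sections, radius_m)
    ok <- se$days_known >= min_days
    if (sum(ok) < min_trimesters) {
      insufficient <- c(insufficient, sid)
      next
    }
    kg_mat <- matrix(0, 3, length(chems), dimnames = list(NULL, chems))
    if (nrow(se$by_trimester) > 0) {
      kg_mat[cbind(se$by_trimester$trimester,
                   match(se$by_trimester$chemical, chems))] <- se$by_trimester$kg
    }
    est[si, ] <- colSums(kg_mat[ok, , drop = FALSE]) / sum(ok)
  }
  keep <- !(subjects %in% insufficient)
  est <- est[keep, , drop = FALSE]
  if (nrow(est) == 0) abort("no subject met the pregnancy-average sufficiency rule")

  retained <- if (apply_filter) inclusion_filter(est) else {
    structure(chems, report = NULL)
  }
  filter_report <- attr(retained, "report")
  cont <- est[, as.character(retained), drop = FALSE]
  cumulative <- rowSums(cont)
  profiles <- matrix(0L, nrow(cont), ncol(cont),
                     dimnames = dimnames(cont))
  cuts <- vector("list", ncol(cont))
  names(cuts) <- colnames(cont)
  for (j in seq_len(ncol(cont))) {
    dj <- quartile_discretize(cont[, j])
    profiles[, j] <- dj
    cuts[[j]] <- attr(dj, "cuts")
  }
  structure(list(
    continuous = dplyr::bind_cols(
      tibble(subject_id = rownames(cont)), as_tibble(cont),
      tibble(cumulative = cumulative)),
    profiles = profiles,
    cumulative = cumulative,
    cuts = cuts,
    retained = as.character(retained),
    excluded_subjects = insufficient,
    filter_report = filter_report,
    radius_m = radius_m
  ), class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf(
    "Exposure table: %d subjects, %d retained pesticides (%d excluded subjects)\n",
    nrow(x$profiles), length(x$retained), length(x$excluded_subjects)))
  invisible(x)
}

#' Write an exposure table and its filter report
#'
#' @param x An `exposure_table`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_exposure_table <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cont_path <- file.path(dir, "exposure_continuous.csv")
  prof_path <- file.path(dir, "exposure_profiles.csv")
  rep_path <- file.path(dir, "filter_report.txt")
  write.csv(x$continuous, cont_path, row.names = FALSE)
  write.csv(dplyr::bind_cols(tibble(subject_id = rownames(x$profiles)),
                             as_tibble(x$profiles)),
            prof_path, row.names = FALSE)
  lines <- c(
    sprintf("retained: %s", paste(x$retained, collapse = ", ")),
    sprintf("excluded subjects (insufficient trimesters): %s",
            if (length(x$excluded_subjects)) {
              paste(x$excluded_subjects, collapse = ", ")
            } else "none"))
  if (!is.null(x$filter_report)) {
    lines <- c(lines, utils::capture.output(print(as.data.frame(x$filter_report))))
  }
  writeLines(lines, rep_path)
  invisible(c(cont_path, prof_path, rep_path))
}
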