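# Trajectory post-processing: visit detection, connectivity matrices with
# retention, transit-time distributions, source-density maps, and
# vertical-displacement statistics.

#' Detect closed-area visits along trajectories
#'
#' Horizontal point-in-polygon test per recorded step (depth is ignored:
#' "passing over" semantics). First-arrival time per (particle, area) is the
#' earliest in-polygon step, including the release position at time 0; the
#' terminal area is taken from the last non-removed position. If the
#' trajectory set already carries per-integration-step visit times (from
#' `track_particles(..., areas = )`), those are reused as-is.
#'
#' @param traj A `trajectory_set`.
#' @param areas A [closed_area_set()].
#' @return A `visit_table`: list with `visits` (tibble `particle_id`,
#'   `area_id`, `first_arrival_s`), `particles` (tibble `particle_id`,
#'   `source_area_id`, `terminal_area_id`), and `area_ids`.
#' @export
detect_visits <- function(traj, areas) {
  n_area <- nrow(areas)
  pid <- traj$particles$particle_id

  if (!is.null(traj$visits)) {
    visits <- traj$visits
  } else {
    st <- traj$states |> filter(.data$status != "removed_boundary")
    vis <- vector("list", n_area)
    for (a in seq_len(n_area)) {
      inside <- .points_in_polygon(st$lon, st$lat, areas$polygon[[a]])
      if (any(inside)) {
        vis[[a]] <- st[inside, c("particle_id", "time_s")] |>
          group_by(.data$particle_id) |>
          summarise(first_arrival_s = min(.data$time_s), .groups = "drop") |>
          mutate(area_id = areas$area_id[a])
      }
    }
    visits <- bind_rows(vis)
    if (nrow(visits) == 0) {
      visits <- tibble(particle_id = integer(), first_arrival_s = numeric(),
                       area_id = integer())
    }
    visits <- visits |> select("particle_id", "area_id", "first_arrival_s") |>
      arrange(.data$particle_id, .data$area_id)
  }

  # terminal area from the final (frozen for grounded, last active for
  # removed) position; removed particles terminated outside the domain
  fin <- traj$particles
  terminal <- rep(NA_integer_, nrow(fin))
  not_removed <- fin$status != "removed_boundary"
  for (a in seq_len(n_area)) {
    inside <- .points_in_polygon(fin$final_lon, fin$final_lat, areas$polygon[[a]])
    hit <- inside & not_removed & is.na(terminal)
    terminal[hit] <- areas$area_id[a]
  }
  particles <- tibble(
    particle_id = pid,
    source_area_id = fin$area_id,
    terminal_area_id = terminal
  )
  structure(list(visits = visits, particles = particles,
                 area_ids = areas$area_id),
            class = "visit_table")
}

#' @export
print.visit_table <- function(x, ...) {
  cat(sprintf("<visit_table> %d particles, %d areas, %d visit records\n",
              nrow(x$particles), length(x$area_ids), nrow(x$visits)))
  invisible(x)
}

#' Connectivity matrix with retention
#'
#' Entry (s, r) is the percentage of particles released from source area s
#' that passed over or terminated in receiving area r; the diagonal is
#' retention, counting only particles that *terminated* in their release
#' area (a particle that exits and re-enters before termination still counts
#' as retained). Raw counts and released totals are kept alongside the
#' percentages.
#'
#' @param visit_table A [detect_visits()] result.
#' @param released Optional named vector of released counts per source area;
#'   defaults to tallying the visit table's particles.
#' @param meta Optional named list of scenario metadata (depth, duration,
#'   season, direction) carried along for labelling.
#' @return A `connectivity_matrix`: list with `percent` and `counts`
#'   matrices (sources x receivers), `released`, and `meta`. Sources with
#'   zero released particles are flagged `NA`, not silently zero.
#' @export
connectivity_matrix <- function(visit_table, released = NULL, meta = list()) {
  ids <- visit_table$area_ids
  k <- length(ids)
  pt <- visit_table$particles
  if (anyNA(pt$source_area_id)) {
    .stop_validation("every particle needs a known source area for connectivity")
  }
  if (is.null(released)) {
    released <- table(factor(pt$source_area_id, levels = ids))
    released <- setNames(as.numeric(released), ids)
  } else {
    released <- setNames(as.numeric(released[as.character(ids)]), ids)
    released[is.na(released)] <- 0
  }

  reached <- left_join(visit_table$visits, pt, by = "particle_id")
  counts <- matrix(0, k, k, dimnames = list(source = ids, receiver = ids))
  if (nrow(reached)) {
    # pass over or terminate (off-diagonal); visits include t = 0 entries
    tab <- reached |>
      distinct(.data$particle_id, .data$source_area_id, .data$area_id) |>
      count(.data$source_area_id, .data$area_id)
    counts[cbind(match(tab$source_area_id, ids), match(tab$area_id, ids))] <- tab$n
  }
  # particles that terminated in r but were never caught passing over it
  term <- pt |> filter(!is.na(.data$terminal_area_id))
  if (nrow(term)) {
    in_visits <- paste(reached$particle_id, reached$area_id)
    extra <- term |>
      filter(!paste(.data$particle_id, .data$terminal_area_id) %in% in_visits) |>
      count(.data$source_area_id, .data$terminal_area_id)
    if (nrow(extra)) {
      ij <- cbind(match(extra$source_area_id, ids), match(extra$terminal_area_id, ids))
      counts[ij] <- counts[ij] + extra$n
    }
  }
  # diagonal = retention: terminated in the release area
  ret <- term |> filter(.data$terminal_area_id == .data$source_area_id) |>
    count(.data$source_area_id)
  diag(counts) <- 0
  if (nrow(ret)) {
    ii <- match(ret$source_area_id, ids)
    counts[cbind(ii, ii)] <- ret$n
  }

  percent <- 100 * counts / released
  percent[released == 0, ] <- NA_real_
  if (any(released == 0)) {
    warn(sprintf("source area(s) %s released no particles; rows flagged NA",
                 paste(ids[released == 0], collapse = ", ")),
         class = "capdrift_warning_empty_source")
  }
  structure(list(percent = percent, counts = counts, released = released,
                 meta = meta),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d areas", nrow(x$percent), ncol(x$percent)))
  if (length(x$meta)) {
    cat("  [", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "]")
  }
  cat("\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Transit-time distribution
#'
#' Histogram of first-arrival days into each receiving area, excluding
#' retention (arrivals into the particle's own release area), normalized by
#' the total number of arrivals into that area so each area's bins sum to 1.
#'
#' @param visit_table A [detect_visits()] result.
#' @param bin_width_days Bin width in days.
#' @return A tibble (`area_id`, `day`, `n`, `proportion`) of class
#'   `transit_time_distribution`; empty when there are no non-retention
#'   arrivals.
#' @export
transit_time_distribution <- function(visit_table, bin_width_days = 1) {
  arr <- left_join(visit_table$visits, visit_table$particles, by = "particle_id") |>
    filter(is.na(.data$source_area_id) | .data$area_id != .data$source_area_id)
  out <- if (nrow(arr) == 0) {
    tibble(area_id = integer(), day = numeric(), n = integer(),
           proportion = numeric())
  } else {
    arr |>
      mutate(day = floor(.data$first_arrival_s / 86400 / bin_width_days) *
               bin_width_days) |>
      count(.data$area_id, .data$day) |>
      group_by(.data$area_id) |>
      mutate(proportion = .data$n / sum(.data$n)) |>
      ungroup()
  }
  class(out) <- c("transit_time_distribution", class(out))
  out
}

#' Source-density map
#'
#' Initial positions of particles that later pass over or terminate in any
#' closed area, binned and counted on a regular lon/lat grid (0.1 degrees by
#' default, floor binning). Proportions are counts over the total number of
#' particles released.
#'
#' @param traj A `trajectory_set`.
#' @param areas A [closed_area_set()].
#' @param bin Bin size in degrees.
#' @return A tibble (`lon_bin`, `lat_bin` cell centres, `count`,
#'   `proportion`) of class `source_density_map`, with attributes
#'   `n_released` and `n_qualifying`.
#' @export
source_density_map <- function(traj, areas, bin = 0.1) {
  vt <- detect_visits(traj, areas)
  qual_ids <- union(
    vt$visits$particle_id,
    vt$particles$particle_id[!is.na(vt$particles$terminal_area_id)]
  )
  p <- traj$particles |> filter(.data$particle_id %in% qual_ids)
  n_rel <- nrow(traj$particles)
  out <- if (nrow(p) == 0) {
    tibble(lon_bin = numeric(), lat_bin = numeric(), count = integer(),
           proportion = numeric())
  } else {
    p |>
      mutate(lon_bin = (floor(.data$release_lon / bin) + 0.5) * bin,
             lat_bin = (floor(.data$release_lat / bin) + 0.5) * bin) |>
      count(.data$lon_bin, .data$lat_bin, name = "count") |>
      mutate(proportion = .data$count / n_rel)
  }
  attr(out, "n_released") <- n_rel
  attr(out, "n_qualifying") <- nrow(p)
  class(out) <- c("source_density_map", class(out))
  out
}

#' Vertical-displacement statistics
#'
#' Summarizes the per-particle extreme depths of a run: the deepest maximum
#' and shallowest minimum reached by any particle, and the depths reached by
#' the first 25/50/75% of particles, reading "first p%" as the least
#' extreme p% of the per-particle extreme-depth distribution. On the
#' downward side the p% value is the p-th percentile of the per-particle
#' maximum depths (p% of particles have max depth at or above, i.e. no
#' deeper than, that value); the upward side is mirrored (p% have min depth
#' at or below, i.e. no shallower). Percentiles use median-style linear
#' interpolation.
#'
#' @param traj A `trajectory_set` (or its `particles` tibble).
#' @param percentiles Percentages to report.
#' @return One-row tibble: `n`, `min_depth_reached`, `max_depth_reached`,
#'   and `min_p<q>` / `max_p<q>` columns; `degenerate` flags runs with
#'   fewer than 2 particles.
#' @export
vertical_stats <- function(traj, percentiles = c(25, 50, 75)) {
  p <- if (inherits(traj, "trajectory_set")) traj$particles else traj
  n <- nrow(p)
  maxs <- p$max_depth
  mins <- p$min_depth
  qmax <- quantile(maxs, percentiles / 100, type = 7, names = FALSE)
  qmin <- quantile(mins, 1 - percentiles / 100, type = 7, names = FALSE)
  out <- tibble(
    n = n,
    min_depth_reached = min(mins),
    max_depth_reached = max(maxs),
    degenerate = n < 2
  )
  for (i in seq_along(percentiles)) {
    out[[sprintf("min_p%d", percentiles[i])]] <- qmin[i]
    out[[sprintf("max_p%d", percentiles[i])]] <- qmax[i]
  }
  if (n < 2) {
    warn("fewer than 2 particles: percentiles are degenerate",
         class = "capdrift_warning_degenerate")
  }
  out
}

#' Pearson correlation between two connectivity matrices
#'
#' Pearson's r over the flattened count matrices (retention included), used
#' to compare seasonal and annual-average scenarios.
#'
#' @param m1,m2 [connectivity_matrix()] objects over identical area sets.
#' @return Pearson r (scalar); `NA` with a warning if either matrix has
#'   zero variance.
#' @export
matrix_correlation <- function(m1, m2) {
  if (!identical(dimnames(m1$counts), dimnames(m2$counts))) {
    .stop_validation("connectivity matrices cover different area sets")
  }
  x <- as.vector(m1$counts)
  y <- as.vector(m2$counts)
  if (identical(x, y) && sd(x) > 0) return(1)
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance count vector: correlation undefined",
         class = "capdrift_warning_degenerate")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}
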