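# Water-mass characterization: regridding, per-area bottom series, and
# along-trajectory temperature/salinity sampling.

#' Bilinear horizontal regrid of a scalar field
#'
#' Interpolates each depth level and time slice of a coarse scalar field
#' onto a finer regular lon/lat grid (0.03 degrees in the standard setup).
#' By default strict bilinear: a target node that depends on any masked
#' source cell is masked (no weight renormalization), so the mask propagates
#' conservatively. With `renormalize = TRUE` a target node is wet if any
#' corner is wet and takes the weighted mean of the wet corners; near steep
#' topography this keeps deep levels usable where strict masking would
#' discard them (biasing "bottom" values towards shallow levels).
#'
#' @param field A [scalar_field()].
#' @param target_spacing Target horizontal spacing in degrees.
#' @param bbox Optional `(lon_min, lon_max, lat_min, lat_max)` subregion;
#'   must lie inside the source grid.
#' @param renormalize Renormalize weights over unmasked corners instead of
#'   propagating the mask strictly.
#' @return A [scalar_field()] on the target grid.
#' @export
regrid_linear <- function(field, target_spacing = 0.03, bbox = NULL,
                          renormalize = FALSE) {
  g <- field$grid
  if (is.null(bbox)) {
    bbox <- c(g$lons[1], g$lons[length(g$lons)], g$lats[1], g$lats[length(g$lats)])
  }
  if (bbox[1] < g$lons[1] || bbox[2] > g$lons[length(g$lons)] ||
      bbox[3] < g$lats[1] || bbox[4] > g$lats[length(g$lats)]) {
    abort("target region extends outside the source grid",
          class = "capdrift_error_domain")
  }
  tl <- seq(bbox[1], bbox[2], by = target_spacing)
  tb <- seq(bbox[3], bbox[4], by = target_spacing)
  tg <- ocean_grid(tl, tb, g$depths)
  nx <- length(tl); ny <- length(tb); nz <- length(g$depths)

  pts <- expand.grid(lon = tl, lat = tb)
  lx <- .axis_locate(pts$lon, g$lons)
  ly <- .axis_locate(pts$lat, g$lats)
  snx <- length(g$lons); sny <- length(g$lats)

  vals <- array(NA_real_, c(nx, ny, nz, field$nt))
  wet_t <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    lev_wet <- field$wet[, , k]
    all_wet <- rep(TRUE, nrow(pts))
    wet_wsum <- numeric(nrow(pts))
    for (a in 0:1) {
      wx <- if (a == 0) 1 - lx$f else lx$f
      for (b in 0:1) {
        wy <- if (b == 0) 1 - ly$f else ly$f
        cw <- lev_wet[(lx$i + a) + snx * (ly$i + b - 1L)]
        all_wet <- all_wet & cw
        wet_wsum <- wet_wsum + wx * wy * as.numeric(cw)
      }
    }
    acc_ok <- if (renormalize) wet_wsum > 0 else all_wet
    norm <- if (renormalize) wet_wsum else rep(1, nrow(pts))
    wet_t[, , k] <- matrix(acc_ok, nx, ny)
    for (it in seq_len(field$nt)) {
      lev <- field$values[, , k, it]
      acc <- numeric(nrow(pts))
      for (a in 0:1) {
        wx <- if (a == 0) 1 - lx$f else lx$f
        for (b in 0:1) {
          wy <- if (b == 0) 1 - ly$f else ly$f
          z <- lev[(lx$i + a) + snx * (ly$i + b - 1L)]
          z[is.na(z)] <- 0
          acc <- acc + wx * wy * z
        }
      }
      acc <- acc / norm
      acc[!acc_ok] <- NA_real_
      vals[, , k, it] <- matrix(acc, nx, ny)
    }
  }
  scalar_field(tg, vals, field$variable, time = field$time, wet = wet_t)
}

#' Per-area annual bottom temperature/salinity series
#'
#' For each closed area and each year, the mean, minimum and maximum of the
#' bottom values (deepest unmasked level) over all grid columns whose node
#' lies inside the area polygon and over all 12 months. Columns are
#' unweighted. Areas containing no ocean columns are flagged with a warning
#' and returned with `NA` statistics.
#'
#' @param temperature,salinity Multi-year [scalar_field()]s sharing a grid
#'   and time axis (see [make_ts_climatology()] with `n_years > 1`).
#' @param areas A [closed_area_set()].
#' @return Tibble: `area_id`, `year`, `n_columns`, `t_mean`, `t_min`,
#'   `t_max`, `s_mean`, `s_min`, `s_max`.
#' @export
area_bottom_series <- function(temperature, salinity, areas) {
  stopifnot(identical(temperature$grid$lons, salinity$grid$lons),
            identical(nrow(temperature$time), nrow(salinity$time)))
  g <- temperature$grid
  nodes <- expand.grid(lon = g$lons, lat = g$lats)
  kbot <- .column_bottom_index(temperature$wet)
  years <- unique(temperature$time$year)
  nx <- length(g$lons); ny <- length(g$lats); nz <- length(g$depths)
  sz <- nx * ny * nz

  out <- purrr::map(seq_len(nrow(areas)), function(i) {
    inside <- which(.points_in_polygon(nodes$lon, nodes$lat, areas$polygon[[i]]))
    ij <- arrayInd(inside, c(nx, ny))
    kb <- kbot[ij]
    ocean <- kb > 0
    if (!any(ocean)) {
      warn(sprintf("area %d contains no ocean grid columns", areas$area_id[i]),
           class = "capdrift_warning_empty_area")
      return(tibble(area_id = areas$area_id[i], year = years, n_columns = 0L,
                    t_mean = NA_real_, t_min = NA_real_, t_max = NA_real_,
                    s_mean = NA_real_, s_min = NA_real_, s_max = NA_real_))
    }
    ij <- ij[ocean, , drop = FALSE]
    kb <- kb[ocean]
    lin0 <- ij[, 1] + nx * ((ij[, 2] - 1L) + ny * (kb - 1L))
    purrr::map(years, function(yr) {
      its <- which(temperature$time$year == yr | is.na(yr))
      tv <- as.vector(vapply(its, function(it) temperature$values[lin0 + (it - 1L) * sz],
                             numeric(length(lin0))))
      sv <- as.vector(vapply(its, function(it) salinity$values[lin0 + (it - 1L) * sz],
                             numeric(length(lin0))))
      tibble(area_id = areas$area_id[i], year = yr, n_columns = length(lin0),
             t_mean = mean(tv), t_min = min(tv), t_max = max(tv),
             s_mean = mean(sv), s_min = min(sv), s_max = max(sv))
    }) |> bind_rows()
  })
  bind_rows(out)
}

#' Temperature and salinity along trajectories
#'
#' Samples temperature and salinity at every recorded (non-removed)
#' position of each particle and reports the mean and standard deviation
#' along the pathway, pooled by source area. The standard deviation uses
#' the population convention (N denominator).
#'
#' @param traj A `trajectory_set`.
#' @param temperature,salinity [scalar_field()]s (12-month climatologies).
#' @param start_month Fractional month at release for time interpolation;
#'   defaults to the tracker config's.
#' @return Tibble: `area_id`, `n_samples`, `t_mean`, `t_sd`, `s_mean`,
#'   `s_sd`.
#' @export
track_ts <- function(traj, temperature, salinity, start_month = NULL) {
  start_month <- start_month %||% traj$config$start_month
  dirf <- if (traj$config$direction == "backward") -1 else 1
  st <- traj$states |> filter(.data$status != "removed_boundary")
  tmonth <- (start_month + dirf * st$time_s / MONTH_SECONDS) %% 12
  tt <- sample_scalar(temperature, st$lon, st$lat, st$depth, tmonth)
  ss <- sample_scalar(salinity, st$lon, st$lat, st$depth, tmonth)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble(st[, "particle_id"], t = tt$value, s = ss$value) |>
    left_join(traj$particles[, c("particle_id", "area_id")], by = "particle_id") |>
    filter(is.finite(.data$t) & is.finite(.data$s)) |>
    group_by(.data$area_id) |>
    summarise(n_samples = n(),
              t_mean = mean(.data$t), t_sd = pop_sd(.data$t),
              s_mean = mean(.data$s), s_sd = pop_sd(.data$s),
              .groups = "drop")
}
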