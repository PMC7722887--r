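# Synthetic ocean generator.
#
# A kinematic test ocean with the circulation structure of an isolated
# bathymetric cap: Gaussian seamount relief, an anticyclonic (clockwise)
# slope-following jet whose speed peaks on a chosen isobath, a downwelling
# band on the upper slope with upwelling offshore, seasonal amplitude
# modulation peaking in late summer, and a cold/salty stably stratified
# bottom layer. The horizontal flow is azimuthal about the cap (equivalently,
# derived from a streamfunction that is a function of seafloor depth), hence
# horizontally non-divergent and tangent to isobaths; the vertical velocity
# is prescribed independently, which is acceptable for a kinematic test
# ocean but not dynamically consistent.

#' Parameters of the synthetic cap ocean
#'
#' Defaults give a desk-scale stand-in for the circulation around an
#' isolated cap: a 140 m summit rising from a 4000 m abyssal plain with an
#' 80 km e-folding radius, a clockwise slope jet peaking at 0.1 m/s on the
#' 1000 m isobath, downwelling (peak -3e-4 m/s) over slope seafloor centred
#' on the 1500 m isobath and broad enough to cover the deep releases, with
#' upwelling (peak 1.5e-4 m/s) over the abyssal flank near 3500 m, and a
#' 30% seasonal modulation peaking in August.
#'
#' @param center_lon,center_lat Cap centre (degrees).
#' @param summit_depth,abyss_depth Summit and abyssal seafloor depth (m).
#' @param cap_radius_km e-folding radius of the Gaussian cap (km).
#' @param jet_core_isobath_m Seafloor depth (m) of maximum jet speed.
#' @param jet_width_m Width of the jet in seafloor-depth space (m).
#' @param jet_peak_speed Peak azimuthal speed (m/s).
#' @param w_downwelling_peak Peak downward vertical velocity (m/s, negative).
#' @param w_upwelling_peak Peak upward vertical velocity (m/s, positive).
#' @param downwelling_isobath_m,downwelling_width_m Centre/width (m of
#'   seafloor depth) of the downwelling band.
#' @param upwelling_isobath_m,upwelling_width_m Centre/width of the
#'   offshore upwelling band.
#' @param w_taper_top_m,w_taper_full_m Vertical velocity is zero above
#'   `w_taper_top_m` and ramps linearly to full strength at `w_taper_full_m`.
#' @param seasonal_amplitude Fractional monthly modulation in `[0, 1)`.
#' @param peak_month Calendar month of maximum amplitude.
#' @param rotation_sense `"clockwise"` (anticyclonic, the cap default) or
#'   `"counterclockwise"`.
#' @return A `cap_params` list.
#' @export
cap_params <- function(center_lon = -45, center_lat = 47,
                       summit_depth = 140, abyss_depth = 4000,
                       cap_radius_km = 80,
                       jet_core_isobath_m = 1000, jet_width_m = 800,
                       jet_peak_speed = 0.1,
                       w_downwelling_peak = -3e-4, w_upwelling_peak = 1.5e-4,
                       downwelling_isobath_m = 1500, downwelling_width_m = 1500,
                       upwelling_isobath_m = 3500, upwelling_width_m = 400,
                       w_taper_top_m = 50, w_taper_full_m = 200,
                       seasonal_amplitude = 0.3, peak_month = 8,
                       rotation_sense = c("clockwise", "counterclockwise")) {
  rotation_sense <- arg_match(rotation_sense)
  if (summit_depth >= abyss_depth) {
    .stop_validation("summit_depth must be shallower than abyss_depth")
  }
  if (jet_peak_speed <= 0) .stop_validation("jet_peak_speed must be > 0")
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    .stop_validation("seasonal_amplitude must lie in [0, 1)")
  }
  structure(as.list(environment()), class = "cap_params")
}

#' Default grid spanning the synthetic cap
#'
#' @param params A [cap_params()].
#' @param spacing Horizontal spacing in degrees.
#' @param depths Vertical levels (m).
#' @return An [ocean_grid()].
#' @export
default_cap_grid <- function(params = cap_params(), spacing = 0.1,
                             depths = c(0, 25, 50, 100, 200, 350, 500, 700,
                                        1000, 1400, 1900, 2500, 3200, 4000)) {
  lons <- seq(params$center_lon - 3.5, params$center_lon + 3.5, by = spacing)
  lats <- seq(params$center_lat - 2.2, params$center_lat + 2.2, by = spacing)
  ocean_grid(lons, lats, depths)
}

# local equirectangular metres about the cap centre (fixed reference cosine)
.cap_xy <- function(params, lon, lat) {
  kx <- pi * EARTH_RADIUS / 180 * cos(params$center_lat * pi / 180)
  ky <- pi * EARTH_RADIUS / 180
  list(x = (lon - params$center_lon) * kx, y = (lat - params$center_lat) * ky)
}

.cap_depth <- function(params, lon, lat) {
  xy <- .cap_xy(params, lon, lat)
  R2 <- (params$cap_radius_km * 1000)^2
  r2 <- xy$x^2 + xy$y^2
  params$abyss_depth - (params$abyss_depth - params$summit_depth) * exp(-r2 / R2)
}

# analytic horizontal gradient of seafloor depth (m per m)
.cap_depth_grad <- function(params, lon, lat) {
  xy <- .cap_xy(params, lon, lat)
  R2 <- (params$cap_radius_km * 1000)^2
  r2 <- xy$x^2 + xy$y^2
  g <- (params$abyss_depth - params$summit_depth) * exp(-r2 / R2) * 2 / R2
  list(hx = g * xy$x, hy = g * xy$y)
}

# radius (m) of a given isobath on the Gaussian cap
.cap_isobath_radius <- function(params, h) {
  span <- params$abyss_depth - params$summit_depth
  if (h <= params$summit_depth || h >= params$abyss_depth) {
    .stop_validation("isobath %g m outside (summit, abyss) = (%g, %g)",
                     h, params$summit_depth, params$abyss_depth)
  }
  params$cap_radius_km * 1000 * sqrt(log(span / (params$abyss_depth - h)))
}

#' Gaussian seamount bathymetry
#'
#' `seafloor = abyss - (abyss - summit) * exp(-r^2 / R^2)` with `r` the
#' distance from the cap centre and `R` the e-folding radius, so the relief
#' is radially monotone and reaches the abyssal depth within 1% by `r = 3R`.
#'
#' @param params A [cap_params()].
#' @param grid An [ocean_grid()] (or anything with `lons`/`lats`).
#' @return A [bathymetry()].
#' @export
make_seamount_bathymetry <- function(params = cap_params(),
                                     grid = default_cap_grid(params)) {
  ll <- expand.grid(lon = grid$lons, lat = grid$lats)
  z <- .cap_depth(params, ll$lon, ll$lat)
  bathymetry(grid$lons, grid$lats,
             matrix(z, length(grid$lons), length(grid$lats)))
}

# monthly amplitude factor: 1 + A cos(2 pi (m - peak) / 12)
.season_factor <- function(month, params) {
  1 + params$seasonal_amplitude * cos(2 * pi * (month - params$peak_month) / 12)
}

# vertical-velocity magnitude as a function of seafloor depth and sample depth
.cap_w <- function(params, h, z) {
  band <- params$w_downwelling_peak *
    exp(-((h - params$downwelling_isobath_m) / params$downwelling_width_m)^2) +
    params$w_upwelling_peak *
    exp(-((h - params$upwelling_isobath_m) / params$upwelling_width_m)^2)
  taper <- pmin(pmax((z - params$w_taper_top_m) /
                       (params$w_taper_full_m - params$w_taper_top_m), 0), 1)
  band * taper
}

#' Idealized circulation around the cap
#'
#' Horizontal velocity is azimuthal about the cap (tangent to isobaths,
#' hence horizontally non-divergent) with speed
#' `jet_peak_speed * exp(-((h - jet_core) / jet_width)^2)` where `h` is the
#' local seafloor depth; the sense is clockwise for
#' `rotation_sense = "clockwise"`. Vertical velocity is downward over the
#' upper-slope band and upward offshore, zero in the surface layer. Monthly
#' slices are scaled by `1 + A cos(2 pi (m - peak_month)/12)`, so summer and
#' autumn slices are the strongest with the default August peak.
#'
#' @param bathy Bathymetry from [make_seamount_bathymetry()] (must share the
#'   analytic cap of `params`).
#' @param params A [cap_params()].
#' @param depths Vertical levels of the flow grid (m).
#' @param months Climatological months to generate, or `NA` for a steady
#'   annual-mean field.
#' @return A [flow_field()].
#' @export
make_cap_circulation <- function(bathy, params = cap_params(),
                                 depths = c(0, 25, 50, 100, 200, 350, 500, 700,
                                            1000, 1400, 1900, 2500, 3200, 4000),
                                 months = 1:12) {
  if (params$jet_core_isobath_m <= params$summit_depth ||
      params$jet_core_isobath_m >= params$abyss_depth) {
    .stop_validation("jet_core_isobath_m (%g) must lie between summit (%g) and abyss (%g)",
                     params$jet_core_isobath_m, params$summit_depth, params$abyss_depth)
  }
  grid <- ocean_grid(bathy$lons, bathy$lats, depths)
  nx <- length(grid$lons); ny <- length(grid$lats); nz <- length(grid$depths)
  steady <- length(months) == 1 && is.na(months)
  nt <- if (steady) 1L else length(months)

  ll <- expand.grid(lon = grid$lons, lat = grid$lats)
  h <- .cap_depth(params, ll$lon, ll$lat)
  gr <- .cap_depth_grad(params, ll$lon, ll$lat)
  gmag <- sqrt(gr$hx^2 + gr$hy^2)
  speed <- params$jet_peak_speed *
    exp(-((h - params$jet_core_isobath_m) / params$jet_width_m)^2)
  sense <- if (params$rotation_sense == "clockwise") 1 else -1
  # clockwise unit tangent to isobaths: (h_y, -h_x) / |grad h|
  tx <- ifelse(gmag > 1e-12, gr$hy / gmag, 0)
  ty <- ifelse(gmag > 1e-12, -gr$hx / gmag, 0)
  u2 <- sense * speed * tx   # (nx*ny)
  v2 <- sense * speed * ty

  wet <- array(FALSE, c(nx, ny, nz))
  seafloor <- as.vector(bathy$seafloor_depth)
  for (k in seq_len(nz)) {
    wet[, , k] <- matrix(is.finite(seafloor) & grid$depths[k] <= seafloor, nx, ny)
  }

  u <- array(NA_real_, c(nx, ny, nz, nt))
  v <- array(NA_real_, c(nx, ny, nz, nt))
  w <- array(NA_real_, c(nx, ny, nz, nt))
  fac <- if (steady) 1 else .season_factor(months, params)
  for (t in seq_len(nt)) {
    for (k in seq_len(nz)) {
      wk <- .cap_w(params, h, grid$depths[k])
      u[, , k, t] <- matrix(fac[t] * u2, nx, ny)
      v[, , k, t] <- matrix(fac[t] * v2, nx, ny)
      w[, , k, t] <- matrix(fac[t] * wk, nx, ny)
    }
  }
  flow_field(grid, u, v, w, months = months, wet = wet)
}

#' Analytic oracle flows
#'
#' Exactly evaluable flows used as integration oracles: `"zero"`,
#' `"uniform"` (constant `u0`, `v0`, `w0`), and `"solid_rotation"`
#' (`u = -omega * y`, `v = omega * x` in local metres about
#' `center_lon`/`center_lat`, `w = 0`, giving speed `omega * r` and circular
#' trajectories of period `2 pi / omega`). The returned object samples the
#' closed form directly (no grid truncation); pass `grid` to evaluate it
#' onto a regular [flow_field()] instead. The solid rotation carries the
#' spherical-metric factor `cos(lat)/cos(center_lat)` on `u` so trajectories
#' are exact circles in local-metre coordinates at any latitude.
#'
#' @param kind One of `"zero"`, `"uniform"`, `"solid_rotation"`.
#' @param params Named list: `u0`, `v0`, `w0` for `"uniform"`; `omega`
#'   (rad/s), `center_lon`, `center_lat` for `"solid_rotation"`.
#' @param grid Optional [ocean_grid()] to rasterize onto.
#' @return An `analytic_flow` (also a `flow_field` for dispatch), or a
#'   gridded [flow_field()] when `grid` is given.
#' @export
make_analytic_flow <- function(kind = c("zero", "uniform", "solid_rotation"),
                               params = list(), grid = NULL) {
  kind <- arg_match(kind)
  p <- params
  fun <- switch(
    kind,
    zero = function(lon, lat, depth, t) {
      z <- numeric(length(lon))
      list(u = z, v = z, w = z)
    },
    uniform = {
      u0 <- p$u0 %||% 0; v0 <- p$v0 %||% 0; w0 <- p$w0 %||% 0
      function(lon, lat, depth, t) {
        o <- rep(1, length(lon))
        list(u = u0 * o, v = v0 * o, w = w0 * o)
      }
    },
    solid_rotation = {
      omega <- p$omega %||% 1e-4
      clon <- p$center_lon %||% -45
      clat <- p$center_lat %||% 0
      kx <- pi * EARTH_RADIUS / 180 * cos(clat * pi / 180)
      ky <- pi * EARTH_RADIUS / 180
      function(lon, lat, depth, t) {
        x <- (lon - clon) * kx
        y <- (lat - clat) * ky
        metric <- cos(lat * pi / 180) / cos(clat * pi / 180)
        list(u = -omega * y * metric, v = omega * x, w = numeric(length(lon)))
      }
    }
  )
  if (!is.null(grid)) {
    ll <- expand.grid(lon = grid$lons, lat = grid$lats)
    s <- fun(ll$lon, ll$lat, 0, 0)
    nx <- length(grid$lons); ny <- length(grid$lats); nz <- length(grid$depths)
    rep3 <- function(x) array(rep(x, nz), c(nx, ny, nz, 1))
    return(flow_field(grid, rep3(s$u), rep3(s$v), rep3(s$w), months = NA))
  }
  structure(list(kind = kind, params = p, fun = fun),
            class = c("analytic_flow", "flow_field"))
}

#' @export
.velocity_at.analytic_flow <- function(field, lon, lat, depth, time_of_year) {
  s <- field$fun(lon, lat, depth, time_of_year)
  bad <- !is.finite(lon) | !is.finite(lat)
  status <- rep(STATUS_OK, length(lon))
  status[bad] <- STATUS_OUT_OF_DOMAIN
  s$u[bad] <- NA_real_; s$v[bad] <- NA_real_; s$w[bad] <- NA_real_
  list(u = s$u, v = s$v, w = s$w, status = status)
}

#' @export
print.analytic_flow <- function(x, ...) {
  cat(sprintf("<analytic_flow> kind = %s\n", x$kind))
  invisible(x)
}

#' Synthetic temperature and salinity climatology
#'
#' Depth-decreasing temperature and depth-increasing salinity profiles with
#' a surface-intensified seasonal cycle, tuned so bottom water on the slope
#' is cold (< 4 degC) and salty (> 34.8) at the depths of the closure
#' fixtures, emulating the stable bottom water masses of the region.
#' Optional interannual noise (a spatially uniform Gaussian perturbation per
#' year-month) supports multi-year stability analyses; the generator is
#' deterministic given `seed`.
#'
#' @param bathy A [bathymetry()].
#' @param params A [cap_params()] (used for the grid extent only).
#' @param depths Vertical levels (m).
#' @param n_years Number of years; 1 gives a plain 12-month climatology.
#' @param start_year First year label for multi-year series.
#' @param noise_sd_t,noise_sd_s Std dev of the interannual noise (degC, psu).
#' @param seed RNG seed for the noise draws.
#' @return A list with elements `temperature` and `salinity`
#'   ([scalar_field()]s).
#' @export
make_ts_climatology <- function(bathy, params = cap_params(),
                                depths = c(0, 25, 50, 100, 200, 350, 500, 700,
                                           1000, 1400, 1900, 2500, 3200, 4000),
                                n_years = 1, start_year = 2000,
                                noise_sd_t = 0.05, noise_sd_s = 0.005,
                                seed = 1L) {
  grid <- ocean_grid(bathy$lons, bathy$lats, depths)
  nx <- length(grid$lons); ny <- length(grid$lats); nz <- length(grid$depths)
  nt <- 12L * n_years
  time <- tibble(
    year = if (n_years == 1) rep(NA_integer_, 12) else
      rep(start_year + seq_len(n_years) - 1L, each = 12L),
    month = rep(1:12, times = n_years)
  )

  wet <- array(FALSE, c(nx, ny, nz))
  seafloor <- as.vector(bathy$seafloor_depth)
  for (k in seq_len(nz)) {
    wet[, , k] <- matrix(is.finite(seafloor) & grid$depths[k] <= seafloor, nx, ny)
  }

  # mean vertical structure: warm fresh surface over cold salty deep water
  t_deep <- 2.5; t_surf <- 12; zscale_t <- 250
  s_deep <- 34.92; s_surf <- 33.8; zscale_s <- 150
  t_prof <- t_deep + (t_surf - t_deep) * exp(-grid$depths / zscale_t)
  s_prof <- s_deep - (s_deep - s_surf) * exp(-grid$depths / zscale_s)
  # surface-intensified seasonal cycle, peak in September
  seas_amp <- 3 * exp(-grid$depths / 80)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  noise_t <- rnorm(nt, 0, noise_sd_t)
  noise_s <- rnorm(nt, 0, noise_sd_s)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  tv <- array(NA_real_, c(nx, ny, nz, nt))
  sv <- array(NA_real_, c(nx, ny, nz, nt))
  for (it in seq_len(nt)) {
    m <- time$month[it]
    cyc <- cos(2 * pi * (m - 9) / 12)
    for (k in seq_len(nz)) {
      tv[, , k, it] <- t_prof[k] + seas_amp[k] * cyc + noise_t[it]
      sv[, , k, it] <- s_prof[k] + noise_s[it]
    }
  }
  list(
    temperature = scalar_field(grid, tv, "temperature", time = time, wet = wet),
    salinity = scalar_field(grid, sv, "salinity", time = time, wet = wet)
  )
}

# annular-sector polygon between two isobaths of the cap
.sector_polygon <- function(params, h_in, h_out, az0, az1, n_arc = 9) {
  r_in <- .cap_isobath_radius(params, h_in)
  r_out <- .cap_isobath_radius(params, h_out)
  az <- seq(az0, az1, length.out = n_arc) * pi / 180
  kx <- pi * EARTH_RADIUS / 180 * cos(params$center_lat * pi / 180)
  ky <- pi * EARTH_RADIUS / 180
  x <- c(r_out * cos(az), r_in * cos(rev(az)))
  y <- c(r_out * sin(az), r_in * sin(rev(az)))
  poly <- cbind(lon = params$center_lon + x / kx,
                lat = params$center_lat + y / ky)
  poly
}

# fixture layout: azimuth span (degrees, math convention) and seafloor
# depth range per area; azimuth-overlapping pairs have disjoint depth ranges
.AREA_LAYOUT <- data.frame(
  area_id = 1:14,
  az0 = c(-160, -130, -60, -16, 32, 75, 110, 133, 156, 179, 202, 287, 329, 63),
  az1 = c(-140, -75, -32, 16, 62, 105, 128, 151, 174, 197, 220, 299, 343, 74),
  h_min = c(1000, 483, 1000, 1200, 1000, 1000, 560, 555, 560, 600, 600, 620, 700, 520),
  h_max = c(1400, 1750, 1800, 2800, 2100, 2300, 720, 725, 730, 950, 950, 950, 1300, 688)
)

.AREA_GROUPS <- list(
  sponge = 1:6,
  sea_pen = c(2, 7:12, 14),
  gorgonian = c(2, 4, 5, 13)
)

#' Fixture closed areas on the synthetic cap
#'
#' Fourteen annular-sector stand-ins for the real closure polygons, placed
#' on the synthetic slope so their seafloor depth ranges bracket the
#' release-depth presets: the six sponge areas (1-6) span the deep slope,
#' the sea-pen areas (2, 7-12, 14) sit in shallower water (areas 7 and 14
#' have maximum depths near 700 m, so deep releases cannot enter them), and
#' the gorgonian areas are 2, 4, 5 and 13. These are geometric fixtures,
#' not real closure coordinates; real polygons can be supplied via
#' [read_areas_geojson()].
#'
#' @param params A [cap_params()].
#' @param bathy Optional [bathymetry()]; used to verify the vertices lie
#'   over ocean.
#' @return A [closed_area_set()] with 14 areas.
#' @export
make_closed_areas <- function(params = cap_params(), bathy = NULL) {
  lay <- .AREA_LAYOUT
  rows <- purrr::map(seq_len(nrow(lay)), function(i) {
    poly <- .sector_polygon(params, lay$h_min[i], lay$h_max[i],
                            lay$az0[i], lay$az1[i])
    grp <- names(.AREA_GROUPS)[purrr::map_lgl(.AREA_GROUPS, ~ lay$area_id[i] %in% .x)]
    tibble(area_id = lay$area_id[i], groups = list(grp),
           min_depth = lay$h_min[i], max_depth = lay$h_max[i],
           polygon = list(poly))
  })
  out <- closed_area_set(bind_rows(rows))
  if (!is.null(bathy)) {
    for (i in seq_len(nrow(out))) {
      z <- .bathy_at(bathy, out$polygon[[i]][, 1], out$polygon[[i]][, 2])
      if (anyNA(z)) .stop_validation("area %d has vertices off the ocean grid", out$area_id[i])
    }
  }
  out
}

#' Polygon ring between two isobaths
#'
#' Convenience annulus covering all azimuths between the `h_min` and
#' `h_max` isobaths of the synthetic cap; useful for seeding the
#' upper-slope band.
#'
#' @param params A [cap_params()].
#' @param h_min,h_max Bounding seafloor depths (m).
#' @param n Vertices per arc.
#' @return A 2-column `lon`/`lat` matrix (open ring).
#' @export
isobath_annulus <- function(params, h_min, h_max, n = 72) {
  .sector_polygon(params, h_min, h_max, 0, 359.999, n_arc = n)
}

# season -> climatological months (DJF convention)
SEASON_MONTHS <- list(
  winter = c(12, 1, 2), spring = 3:5, summer = 6:8, autumn = 9:11
)

#' Collapse a monthly flow field to a steady seasonal or annual mean
#'
#' @param field A monthly [flow_field()].
#' @param season `"average"` (all 12 months) or one of `"winter"`,
#'   `"spring"`, `"summer"`, `"autumn"` (DJF/MAM/JJA/SON).
#' @return A steady (single-slice) [flow_field()].
#' @export
season_mean <- function(field, season = "average") {
  if (field$nt == 1) return(field)
  months <- if (identical(season, "average")) 1:12 else {
    if (!season %in% names(SEASON_MONTHS)) {
      .stop_validation("unknown season '%s'", season)
    }
    SEASON_MONTHS[[season]]
  }
  idx <- match(months, field$months)
  if (anyNA(idx)) .stop_validation("field lacks months required for season '%s'", season)
  avg <- function(arr) {
    out <- arr[, , , idx, drop = FALSE]
    array(rowMeans(matrix(out, ncol = length(idx))), c(dim(arr)[1:3], 1))
  }
  flow_field(field$grid, avg(field$u), avg(field$v), avg(field$w),
             months = NA, wet = field$wet)
}
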