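# Shared fixtures, built in code and cached for the session.

# internal helpers exercised directly by the tests
.bathy_at <- capdrift:::.bathy_at
.cap_depth <- capdrift:::.cap_depth
.cap_isobath_radius <- capdrift:::.cap_isobath_radius
.points_in_polygon <- capdrift:::.points_in_polygon

.fix_cache <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (is.null(.fix_cache[[name]])) .fix_cache[[name]] <- builder()
  .fix_cache[[name]]
}

fix_params <- function() fix("params", function() cap_params())
fix_bathy <- function() fix("bathy", function() make_seamount_bathymetry(fix_params()))
fix_flow_monthly <- function() {
  fix("flow_monthly", function() make_cap_circulation(fix_bathy(), fix_params()))
}
fix_flow_steady <- function() {
  fix("flow_steady", function() season_mean(fix_flow_monthly(), "average"))
}
fix_areas <- function() {
  fix("areas", function() make_closed_areas(fix_params(), fix_bathy()))
}

cap_domain_box <- function() {
  g <- fix_bathy()
  c(min(g$lons), max(g$lons), min(g$lats), max(g$lats))
}

# great-circle-free local distance in metres (small separations)
dist_m <- function(lon1, lat1, lon2, lat2) {
  kx <- pi * 6371000 / 180
  sqrt(((lon2 - lon1) * kx * cos(lat1 * pi / 180))^2 + ((lat2 - lat1) * kx)^2)
}

# small uniform grid with constant or user-set arrays, all wet
small_flow <- function(u = 0.1, v = 0, w = 0, nt = 1,
                       lons = seq(-46, -44, 0.5), lats = seq(46, 48, 0.5),
                       depths = c(0, 100, 500, 1500)) {
  grid <- ocean_grid(lons, lats, depths)
  dm <- c(length(lons), length(lats), length(depths), nt)
  mk <- function(x) if (length(x) == 1) array(x, dm) else x
  flow_field(grid, mk(u), mk(v), mk(w),
             months = if (nt == 1) NA else seq_len(nt))
}

# hand-built trajectory set (bypasses the tracker) for statistics tests
manual_traj <- function(states, particles, dt = 1200, duration_days = 1) {
  cfg <- tracker_config(dt = dt, duration_days = duration_days, K_h = 0)
  structure(list(states = states, particles = particles, config = cfg,
                 visits = NULL),
            class = "trajectory_set")
}

square_area <- function(id, lon0, lat0, half = 0.25, groups = "sponge",
                        dmin = 100, dmax = 2000) {
  tibble::tibble(
    area_id = id, groups = list(groups), min_depth = dmin, max_depth = dmax,
    polygon = list(cbind(lon = c(lon0 - half, lon0 + half, lon0 + half, lon0 - half),
                         lat = c(lat0 - half, lat0 - half, lat0 + half, lat0 + half)))
  )
}

three_square_areas <- function() {
  closed_area_set(dplyr::bind_rows(
    square_area(1L, -45.5, 46.5),
    square_area(2L, -44.5, 46.5),
    square_area(3L, -45.0, 47.5)
  ))
}
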