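# Lagrangian engine: RK4 advection + horizontal random-walk diffusion,
# forward or backward in time, with boundary removal and vertical clamping.

#' Tracker configuration
#'
#' Defaults follow the standard deep-sea dispersal setup: a 20-minute time
#' step, horizontal mixing of 100 m^2/s, and removal of particles at the
#' edge of the model domain (31.4-73.9 W, 40.8-70.5 N by default).
#'
#' @param dt Integration time step in seconds.
#' @param K_h Horizontal diffusivity (m^2/s); the random walk draws
#'   independent Gaussian steps of standard deviation `sqrt(2 * K_h * dt)`
#'   metres per horizontal axis. There is no vertical diffusion.
#' @param direction `"forward"` or `"backward"`. Backward runs negate the
#'   field velocity and step the climatological time argument backwards; the
#'   random walk keeps its forward (sign-symmetric) form.
#' @param duration_days Tracking duration in days (presets: 14, 30, 90).
#' @param seed Integer RNG seed; one stream per run, consumed in a fixed
#'   particle order, so runs are exactly reproducible.
#' @param record_every Record positions every this many steps (the
#'   per-particle depth extremes are updated at every step regardless).
#' @param domain_box Named or positional vector
#'   `(lon_min, lon_max, lat_min, lat_max)`; particles whose new position
#'   leaves this box (or the field's own grid box) are flagged
#'   `removed_boundary` and frozen.
#' @param start_month Fractional month of year at release, for monthly
#'   climatological forcing.
#' @param earth_radius Earth radius (m) for metric conversions.
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(dt = 1200, K_h = 100,
                           direction = c("forward", "backward"),
                           duration_days = 14, seed = 1L, record_every = 1L,
                           domain_box = c(-73.9, -31.4, 40.8, 70.5),
                           start_month = 0, earth_radius = EARTH_RADIUS) {
  direction <- arg_match(direction)
  if (dt <= 0) .stop_validation("dt must be > 0")
  if (K_h < 0) .stop_validation("K_h must be >= 0")
  if (duration_days <= 0) .stop_validation("duration must be > 0")
  if (length(domain_box) != 4) .stop_validation("domain_box needs 4 values")
  domain_box <- as.numeric(domain_box)
  names(domain_box) <- c("lon_min", "lon_max", "lat_min", "lat_max")
  structure(
    list(dt = dt, K_h = K_h, direction = direction,
         duration_days = duration_days, seed = as.integer(seed),
         record_every = as.integer(record_every), domain_box = domain_box,
         start_month = start_month, earth_radius = earth_radius),
    class = "tracker_config"
  )
}

# worst status across RK4 stages: out-of-domain dominates, then grounded
.combine_status <- function(...) {
  codes <- cbind(...)
  out <- rep(STATUS_OK, nrow(codes))
  out[apply(codes == STATUS_GROUNDED, 1, any)] <- STATUS_GROUNDED
  out[apply(codes == STATUS_OUT_OF_DOMAIN, 1, any)] <- STATUS_OUT_OF_DOMAIN
  out
}

#' One RK4 displacement
#'
#' Standard fourth-order Runge-Kutta displacement over the interpolated
#' velocity, vectorized over particles. Velocities are converted to angular
#' rates with `dlat = dy / R * 180 / pi` and
#' `dlon = dx / (R cos(lat)) * 180 / pi`; the vertical contribution is
#' `ddepth = -w * dt` (depth is positive down, `w` positive up). Backward
#' integration negates the velocity and runs the time argument backwards.
#'
#' @param field A flow field (gridded or analytic).
#' @param lon,lat,depth Current positions (vectors).
#' @param t Fractional month of year at the start of the step.
#' @param dt Step length (s).
#' @param direction `"forward"` or `"backward"`.
#' @param earth_radius Earth radius (m).
#' @return A list with `dlon`, `dlat`, `ddepth` (NA where a stage sample
#'   failed) and integer `status` (0 ok, 1 out-of-domain, 2 grounded).
#' @export
rk4_displacement <- function(field, lon, lat, depth, t = 0, dt = 1200,
                             direction = "forward",
                             earth_radius = EARTH_RADIUS) {
  dirf <- if (identical(direction, "backward")) -1 else 1
  dt_month <- dt / MONTH_SECONDS

  rate <- function(lon_s, lat_s, dep_s, frac) {
    s <- .velocity_at(field, lon_s, lat_s, dep_s,
                      (t + dirf * frac * dt_month) %% 12)
    coslat <- cos(lat_s * pi / 180)
    list(
      dlon = dirf * s$u / (earth_radius * coslat) * 180 / pi,
      dlat = dirf * s$v / earth_radius * 180 / pi,
      ddep = -dirf * s$w,
      status = s$status
    )
  }

  k1 <- rate(lon, lat, depth, 0)
  k2 <- rate(lon + k1$dlon * dt / 2, lat + k1$dlat * dt / 2,
             depth + k1$ddep * dt / 2, 0.5)
  k3 <- rate(lon + k2$dlon * dt / 2, lat + k2$dlat * dt / 2,
             depth + k2$ddep * dt / 2, 0.5)
  k4 <- rate(lon + k3$dlon * dt, lat + k3$dlat * dt,
             depth + k3$ddep * dt, 1)

  status <- .combine_status(k1$status, k2$status, k3$status, k4$status)
  wsum <- function(f) (k1[[f]] + 2 * k2[[f]] + 2 * k3[[f]] + k4[[f]]) / 6 * dt
  dlon <- wsum("dlon"); dlat <- wsum("dlat"); ddep <- wsum("ddep")
  bad <- status != STATUS_OK
  dlon[bad] <- NA_real_; dlat[bad] <- NA_real_; ddep[bad] <- NA_real_
  list(dlon = dlon, dlat = dlat, ddepth = ddep, status = status)
}

#' Random-walk diffusion displacement
#'
#' Independent Gaussian increments per horizontal axis with standard
#' deviation `sqrt(2 * K_h * dt)` metres, converted to degrees at the
#' particle latitude. Draws come from R's global RNG stream (seed the run
#' via [tracker_config()]); no vertical diffusion.
#'
#' @param n Number of particles.
#' @param K_h Horizontal diffusivity (m^2/s).
#' @param dt Step length (s).
#' @param lat Particle latitudes (degrees).
#' @param earth_radius Earth radius (m).
#' @return List with `dlon`, `dlat` in degrees.
#' @export
diffusion_displacement <- function(n, K_h, dt, lat,
                                   earth_radius = EARTH_RADIUS) {
  if (K_h <= 0) {
    z <- numeric(n)
    return(list(dlon = z, dlat = z))
  }
  sd_m <- sqrt(2 * K_h * dt)
  dx <- rnorm(n, 0, sd_m)
  dy <- rnorm(n, 0, sd_m)
  list(dlon = dx * .deg_per_m_lon(lat, earth_radius),
       dlat = dy * .deg_per_m_lat(earth_radius))
}

#' Track particles through a flow field
#'
#' Integrates every seed for the configured duration or until removal,
#' recording positions every `record_every` steps and per-particle depth
#' extremes at every step. A particle whose new position leaves the domain
#' box (or the field's grid box) is flagged `removed_boundary` and frozen; a
#' particle over a land/fully-masked column is flagged `grounded`. Particle
#' depth is clamped to `[0, seafloor]` when a bathymetry is supplied
#' (particles ride the seabed rather than being removed). Particle count is
#' conserved: at every recorded step, active + removed + grounded equals the
#' number seeded.
#'
#' @param seeds Tibble of release positions with columns `lon`, `lat`,
#'   `depth` and optionally `particle_id`, `area_id` (see [seed_polygon()]).
#' @param field A flow field (gridded or analytic).
#' @param config A [tracker_config()].
#' @param bathy Optional [bathymetry()] for vertical clamping and grounding.
#' @param areas Optional [closed_area_set()]: when supplied, first-arrival
#'   times into every area are recorded at every integration step (not just
#'   recorded steps), so thin polygons cannot be jumped silently.
#' @return A `trajectory_set`: list with `states` (long tibble of recorded
#'   positions), `particles` (per-particle summary incl. `min_depth`,
#'   `max_depth`), `config`, and `visits` (first-arrival tibble or `NULL`).
#' @export
track_particles <- function(seeds, field, config = tracker_config(),
                            bathy = NULL, areas = NULL) {
  if (!is.data.frame(seeds) || nrow(seeds) == 0) {
    .stop_validation("need at least one seed particle")
  }
  n <- nrow(seeds)
  pid <- if ("particle_id" %in% names(seeds)) seeds$particle_id else seq_len(n)
  src <- if ("area_id" %in% names(seeds)) seeds$area_id else rep(NA_integer_, n)

  lon <- as.numeric(seeds$lon)
  lat <- as.numeric(seeds$lat)
  depth <- as.numeric(seeds$depth)
  state <- rep(PSTATE_ACTIVE, n)

  nsteps <- round(config$duration_days * 86400 / config$dt)
  if (abs(nsteps * config$dt - config$duration_days * 86400) > 1e-6) {
    .stop_validation("duration must be a whole number of time steps")
  }
  rec_steps <- seq(0, nsteps, by = config$record_every)
  nrec <- length(rec_steps)

  rec_lon <- matrix(NA_real_, n, nrec)
  rec_lat <- matrix(NA_real_, n, nrec)
  rec_dep <- matrix(NA_real_, n, nrec)
  rec_state <- matrix(PSTATE_ACTIVE, n, nrec)
  irec <- 1L
  rec_lon[, 1] <- lon; rec_lat[, 1] <- lat; rec_dep[, 1] <- depth

  min_depth <- depth
  max_depth <- depth
  box <- config$domain_box
  fb <- .field_box(field)

  n_area <- if (is.null(areas)) 0L else nrow(areas)
  first_arrival <- if (n_area) matrix(NA_real_, n, n_area) else NULL
  if (n_area) {
    for (a in seq_len(n_area)) {
      inside <- .points_in_polygon(lon, lat, areas$polygon[[a]])
      first_arrival[inside, a] <- 0
    }
  }

  set.seed(config$seed)
  t_field <- config$start_month
  dirf <- if (config$direction == "backward") -1 else 1
  dt_month <- config$dt / MONTH_SECONDS

  for (step in seq_len(nsteps)) {
    act <- which(state == PSTATE_ACTIVE)
    if (length(act)) {
      adv <- rk4_displacement(field, lon[act], lat[act], depth[act],
                              t = t_field, dt = config$dt,
                              direction = config$direction,
                              earth_radius = config$earth_radius)
      dif <- diffusion_displacement(length(act), config$K_h, config$dt,
                                    lat[act], config$earth_radius)
      new_lon <- lon[act] + adv$dlon + dif$dlon
      new_lat <- lat[act] + adv$dlat + dif$dlat
      new_dep <- depth[act] + adv$ddepth

      stat <- adv$status
      # leaving the domain box or the field's grid box removes the particle
      out_box <- !is.na(new_lon) &
        (new_lon < box[1] | new_lon > box[2] |
           new_lat < box[3] | new_lat > box[4] |
           new_lon < fb[1] | new_lon > fb[2] |
           new_lat < fb[3] | new_lat > fb[4])
      stat[out_box] <- STATUS_OUT_OF_DOMAIN

      ok <- stat == STATUS_OK
      idx_ok <- act[ok]
      lon[idx_ok] <- new_lon[ok]
      lat[idx_ok] <- new_lat[ok]
      new_dep_ok <- pmax(new_dep[ok], 0)
      if (!is.null(bathy)) {
        floor_depth <- .bathy_at(bathy, lon[idx_ok], lat[idx_ok])
        landed <- !is.finite(floor_depth)
        new_dep_ok <- ifelse(landed, new_dep_ok, pmin(new_dep_ok, floor_depth))
        if (any(landed)) state[idx_ok[landed]] <- PSTATE_GROUNDED
      }
      depth[idx_ok] <- new_dep_ok
      min_depth[idx_ok] <- pmin(min_depth[idx_ok], new_dep_ok)
      max_depth[idx_ok] <- pmax(max_depth[idx_ok], new_dep_ok)

      state[act[stat == STATUS_OUT_OF_DOMAIN]] <- PSTATE_REMOVED
      state[act[stat == STATUS_GROUNDED]] <- PSTATE_GROUNDED

      if (n_area && length(idx_ok)) {
        t_now <- step * config$dt
        for (a in seq_len(n_area)) {
          cand <- idx_ok[is.na(first_arrival[idx_ok, a])]
          if (length(cand)) {
            inside <- .points_in_polygon(lon[cand], lat[cand], areas$polygon[[a]])
            first_arrival[cand[inside], a] <- t_now
          }
        }
      }
    }
    t_field <- (t_field + dirf * dt_month) %% 12

    if (irec < nrec && step == rec_steps[irec + 1L]) {
      irec <- irec + 1L
      rec_lon[, irec] <- lon
      rec_lat[, irec] <- lat
      rec_dep[, irec] <- depth
      rec_state[, irec] <- state
    }
  }

  states <- tibble(
    particle_id = rep(pid, times = nrec),
    obs = rep(seq_len(nrec), each = n) - 1L,
    time_s = rep(rec_steps * config$dt, each = n),
    lon = as.vector(rec_lon),
    lat = as.vector(rec_lat),
    depth = as.vector(rec_dep),
    status = .pstate_label(as.vector(rec_state))
  )
  particles <- tibble(
    particle_id = pid,
    area_id = src,
    release_lon = as.numeric(seeds$lon),
    release_lat = as.numeric(seeds$lat),
    release_depth = as.numeric(seeds$depth),
    final_lon = lon, final_lat = lat, final_depth = depth,
    min_depth = min_depth, max_depth = max_depth,
    status = .pstate_label(state)
  )
  visits <- NULL
  if (n_area) {
    idx <- which(!is.na(first_arrival), arr.ind = TRUE)
    visits <- tibble(
      particle_id = pid[idx[, 1]],
      area_id = areas$area_id[idx[, 2]],
      first_arrival_s = first_arrival[idx]
    ) |> arrange(.data$particle_id, .data$area_id)
  }
  structure(
    list(states = states, particles = particles, config = config,
         visits = visits),
    class = "trajectory_set"
  )
}

.field_box <- function(field) {
  if (inherits(field, "analytic_flow")) {
    return(c(-Inf, Inf, -Inf, Inf))
  }
  g <- field$grid
  c(g$lons[1], g$lons[length(g$lons)], g$lats[1], g$lats[length(g$lats)])
}

#' @export
print.trajectory_set <- function(x, ...) {
  tab <- table(x$particles$status)
  cat(sprintf(
    "<trajectory_set> %d particles, %d recorded steps, %s %g d (dt = %g s)\n",
    nrow(x$particles), length(unique(x$states$obs)),
    x$config$direction, x$config$duration_days, x$config$dt
  ))
  cat("  status:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
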