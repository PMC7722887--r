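# Experiment orchestration: YAML manifests, scenario grids, reproducible
# CSV outputs.

.default_manifest <- function() {
  list(
    experiment = "vertical_movement",
    seed = 1L,
    ocean = list(synthetic = list()),     # cap_params overrides
    scenarios = list(
      depths = c(0, 100, 450, 1000, 2250),
      durations_days = c(14, 30, 90),
      seasons = "average",
      directions = "forward"
    ),
    seeding = list(spacing = 0.01),
    tracker = list(dt = 1200, K_h = 100, record_every = 1L),
    group = NULL                          # taxon group for connectivity runs
  )
}

#' Read or write a run manifest
#'
#' Manifests are plain YAML holding every number needed to rerun an
#' experiment (parameters, scenario grid, RNG seed); [run_experiment()]
#' copies the completed manifest next to its outputs so a run directory is
#' self-describing.
#'
#' @param path YAML file path.
#' @param manifest Manifest list (for writing).
#' @return The manifest list (read), or `path` invisibly (write).
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

.merge_manifest <- function(manifest) {
  def <- .default_manifest()
  out <- utils::modifyList(def, manifest)
  out
}

.build_ocean <- function(manifest) {
  ov <- manifest$ocean$synthetic %||% list()
  params <- do.call(cap_params, ov)
  spacing <- manifest$ocean$grid_spacing %||% 0.1
  grid <- default_cap_grid(params, spacing = spacing)
  bathy <- make_seamount_bathymetry(params, grid)
  flow <- make_cap_circulation(bathy, params, depths = grid$depths)
  areas <- if (!is.null(manifest$ocean$areas_geojson)) {
    read_areas_geojson(manifest$ocean$areas_geojson)
  } else {
    make_closed_areas(params, bathy)
  }
  list(params = params, grid = grid, bathy = bathy, flow = flow, areas = areas)
}

.scenario_seed <- function(base_seed, idx) {
  as.integer((as.numeric(base_seed) + 1009 * idx) %% 2147483647)
}

.domain_box_of <- function(ocean) {
  g <- ocean$grid
  c(g$lons[1], g$lons[length(g$lons)], g$lats[1], g$lats[length(g$lats)])
}

#' Run a full simulation experiment from a manifest
#'
#' Orchestrates seeding, tracking and statistics over a scenario grid
#' (release depth x duration x season x direction), writing one CSV per
#' statistic plus a copy of the completed manifest to `out_dir`. Rerunning
#' with the same manifest produces byte-identical outputs. Experiments:
#'
#' * `"vertical_movement"`: releases over all closed areas at each preset
#'   depth, forward tracking, [vertical_stats()] per scenario.
#' * `"source_populations"`: domain-wide release at one depth,
#'   [source_density_map()] and per-area arrival proportions.
#' * `"functional_connectivity"`: releases over a taxon group's areas at
#'   the group's preset depths, forward and/or backward,
#'   [connectivity_matrix()] and [transit_time_distribution()].
#' * `"hydrography"`: multi-year synthetic climatology,
#'   [area_bottom_series()] and along-path [track_ts()] for backward runs.
#'
#' A scenario whose release depth exceeds every polygon's seafloor yields a
#' per-scenario warning and the run continues.
#'
#' @param manifest Manifest list or path to a YAML manifest (see
#'   [read_manifest()]); missing entries fall back to defaults.
#' @param out_dir Output directory (created if needed); `NULL` skips CSV
#'   output.
#' @return Invisibly, a named list of result tibbles (also written as CSV).
#' @export
run_experiment <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- .merge_manifest(manifest)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  ocean <- .build_ocean(manifest)
  results <- switch(
    manifest$experiment,
    vertical_movement = .exp_vertical(manifest, ocean),
    source_populations = .exp_sources(manifest, ocean),
    functional_connectivity = .exp_connectivity(manifest, ocean),
    hydrography = .exp_hydrography(manifest, ocean),
    .stop_validation("unknown experiment '%s'", manifest$experiment)
  )
  if (!is.null(out_dir)) {
    for (nm in names(results)) {
      readr::write_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(results)
}

.scenario_field <- function(ocean, season) {
  season_mean(ocean$flow, season)
}

.track_scenario <- function(seeds, field, ocean, manifest, duration, direction,
                            seed, areas = NULL, record_every = NULL) {
  cfg <- tracker_config(
    dt = manifest$tracker$dt, K_h = manifest$tracker$K_h,
    direction = direction, duration_days = duration, seed = seed,
    record_every = record_every %||% manifest$tracker$record_every,
    domain_box = .domain_box_of(ocean)
  )
  track_particles(seeds, field, cfg, bathy = ocean$bathy, areas = areas)
}

.exp_vertical <- function(manifest, ocean) {
  sc <- manifest$scenarios
  grid_df <- expand.grid(depth = sc$depths, duration = sc$durations_days,
                         season = sc$seasons, stringsAsFactors = FALSE)
  out <- purrr::map(seq_len(nrow(grid_df)), function(i) {
    d <- grid_df$depth[i]
    seeds <- withCallingHandlers(
      seed_areas(ocean$areas, manifest$seeding$spacing, d, ocean$bathy),
      capdrift_warning_empty_seed = function(w) invokeRestart("muffleWarning")
    )
    if (nrow(seeds) == 0) {
      warn(sprintf("scenario depth %g m: no area is deep enough; skipped", d))
      return(NULL)
    }
    fld <- .scenario_field(ocean, grid_df$season[i])
    traj <- .track_scenario(seeds, fld, ocean, manifest, grid_df$duration[i],
                            "forward", .scenario_seed(manifest$seed, i),
                            record_every = 1000000L)
    vertical_stats(traj) |>
      mutate(release_depth = d, duration_days = grid_df$duration[i],
             season = grid_df$season[i], .before = 1)
  })
  list(vertical_stats = bind_rows(out))
}

.exp_sources <- function(manifest, ocean) {
  sc <- manifest$scenarios
  depth <- sc$depths[1]
  box <- .domain_box_of(ocean)
  seeds <- seed_domain(box, manifest$seeding$spacing, depth, ocean$bathy)
  out_map <- list()
  out_prop <- list()
  for (i in seq_along(sc$durations_days)) {
    dur <- sc$durations_days[i]
    fld <- .scenario_field(ocean, sc$seasons[1])
    traj <- .track_scenario(seeds, fld, ocean, manifest, dur, sc$directions[1],
                            .scenario_seed(manifest$seed, i),
                            areas = ocean$areas)
    smap <- source_density_map(traj, ocean$areas)
    out_map[[i]] <- as_tibble(smap) |> mutate(duration_days = dur, .before = 1)
    vt <- detect_visits(traj, ocean$areas)
    reach <- vt$visits |> distinct(.data$particle_id, .data$area_id) |>
      count(.data$area_id, name = "n_arrived") |>
      mutate(proportion = .data$n_arrived / nrow(traj$particles),
             duration_days = dur, .before = 1)
    out_prop[[i]] <- reach
  }
  list(source_density = bind_rows(out_map),
       area_proportions = bind_rows(out_prop))
}

.exp_connectivity <- function(manifest, ocean) {
  group <- manifest$group %||% "sponge"
  areas <- areas_in_group(ocean$areas, group)
  sc <- manifest$scenarios
  depths <- sc$depths %||% release_depth_presets()[[group]]
  grid_df <- expand.grid(depth = depths, duration = sc$durations_days,
                         season = sc$seasons, direction = sc$directions,
                         stringsAsFactors = FALSE)
  mats <- list()
  ttds <- list()
  for (i in seq_len(nrow(grid_df))) {
    g <- grid_df[i, ]
    seeds <- withCallingHandlers(
      seed_areas(areas, manifest$seeding$spacing, g$depth, ocean$bathy),
      capdrift_warning_empty_seed = function(w) invokeRestart("muffleWarning")
    )
    if (nrow(seeds) == 0) {
      warn(sprintf("connectivity scenario at %g m: no seeds; skipped", g$depth))
      next
    }
    fld <- .scenario_field(ocean, g$season)
    traj <- .track_scenario(seeds, fld, ocean, manifest, g$duration,
                            g$direction, .scenario_seed(manifest$seed, i),
                            areas = areas)
    vt <- detect_visits(traj, areas)
    cm <- connectivity_matrix(vt, meta = as.list(g))
    mats[[length(mats) + 1L]] <- tidy(cm) |>
      mutate(depth = g$depth, duration_days = g$duration, season = g$season,
             direction = g$direction, .before = 1)
    tt <- transit_time_distribution(vt)
    if (nrow(tt)) {
      ttds[[length(ttds) + 1L]] <- as_tibble(tt) |>
        mutate(depth = g$depth, duration_days = g$duration, season = g$season,
               direction = g$direction, .before = 1)
    }
  }
  list(connectivity = bind_rows(mats), transit_times = bind_rows(ttds))
}

.exp_hydrography <- function(manifest, ocean) {
  hy <- manifest$hydrography %||% list()
  n_years <- hy$n_years %||% 10
  ts <- make_ts_climatology(ocean$bathy, ocean$params,
                            depths = ocean$grid$depths,
                            n_years = n_years,
                            noise_sd_t = hy$noise_sd_t %||% 0.05,
                            noise_sd_s = hy$noise_sd_s %||% 0.005,
                            seed = .scenario_seed(manifest$seed, 1))
  # interpolate onto a fine horizontal grid around the closures before
  # extracting per-area bottom values (thin areas contain no native columns)
  verts <- do.call(rbind, ocean$areas$polygon)
  pad <- 0.15
  bbox <- c(min(verts[, 1]) - pad, max(verts[, 1]) + pad,
            min(verts[, 2]) - pad, max(verts[, 2]) + pad)
  sp_fine <- hy$regrid_spacing %||% 0.03
  t_fine <- regrid_linear(ts$temperature, sp_fine, bbox, renormalize = TRUE)
  s_fine <- regrid_linear(ts$salinity, sp_fine, bbox, renormalize = TRUE)
  series <- area_bottom_series(t_fine, s_fine, ocean$areas)

  # along-pathway T/S for back-tracked releases from each area
  clim <- make_ts_climatology(ocean$bathy, ocean$params,
                              depths = ocean$grid$depths, n_years = 1,
                              noise_sd_t = 0, noise_sd_s = 0,
                              seed = .scenario_seed(manifest$seed, 2))
  depth <- manifest$scenarios$depths[1] %||% 1000
  seeds <- seed_areas(ocean$areas, manifest$seeding$spacing, depth, ocean$bathy)
  fld <- .scenario_field(ocean, manifest$scenarios$seasons[1])
  traj <- .track_scenario(seeds, fld, ocean, manifest,
                          manifest$scenarios$durations_days[1], "backward",
                          .scenario_seed(manifest$seed, 3))
  path_ts <- track_ts(traj, clim$temperature, clim$salinity)
  list(area_bottom_series = series, track_ts = path_ts)
}
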