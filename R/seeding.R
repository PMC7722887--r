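# Uniform particle seeding over polygons or the full domain.

#' Release-depth presets
#'
#' The depth scenarios used by the closure experiments: the
#' vertical-movement experiment releases at the surface, 100, 450, 1000 and
#' 2250 m; the taxon presets are the minimum/middle/maximum of the mean
#' on-bottom depth ranges of each group's areas (sponges 1245/1422/1684 m,
#' sea pens 643/902/1062 m, gorgonians 643/1245/1684 m).
#'
#' @return Named list of numeric depth vectors (m).
#' @export
release_depth_presets <- function() {
  list(
    vertical_movement = c(0, 100, 450, 1000, 2250),
    sponge = c(1245, 1422, 1684),
    sea_pen = c(643, 902, 1062),
    gorgonian = c(643, 1245, 1684)
  )
}

#' Seed particles uniformly over a polygon
#'
#' Candidate positions are a regular lattice at `spacing` degrees anchored
#' at the polygon's bounding-box minimum plus half a spacing (cell centres,
#' half-open on the upper side), intersected with the polygon interior
#' (boundary-touching points excluded). Positions where the seafloor is
#' shallower than the release depth are dropped, so seed counts decrease
#' with release depth under the same spacing. `release_depth = "bottom"`
#' places each particle on the local seafloor.
#'
#' @param polygon 2-column `lon`/`lat` vertex matrix (open ring), or a
#'   single-row [closed_area_set()].
#' @param spacing Lattice spacing in degrees (0.01 in the standard setup;
#'   0.005 for fine back-tracking releases).
#' @param release_depth Release depth in metres, or `"bottom"`.
#' @param bathy A [bathymetry()]; may be `NULL` only for fixed-depth
#'   releases, in which case no depth screening occurs.
#' @param area_id Optional area label attached to the seeds.
#' @return Tibble with columns `particle_id`, `lon`, `lat`, `depth`,
#'   `area_id`. Zero surviving points yields an empty tibble with a warning.
#' @export
seed_polygon <- function(polygon, spacing, release_depth, bathy = NULL,
                         area_id = NA_integer_) {
  if (inherits(polygon, "closed_area_set")) {
    stopifnot(nrow(polygon) == 1)
    area_id <- polygon$area_id[1]
    polygon <- polygon$polygon[[1]]
  }
  if (spacing <= 0) .stop_validation("spacing must be > 0")
  bb_lon <- range(polygon[, 1])
  bb_lat <- range(polygon[, 2])
  lon_c <- seq(bb_lon[1] + spacing / 2, bb_lon[2], by = spacing)
  lat_c <- seq(bb_lat[1] + spacing / 2, bb_lat[2], by = spacing)
  lon_c <- lon_c[lon_c < bb_lon[2]]
  lat_c <- lat_c[lat_c < bb_lat[2]]
  cand <- expand.grid(lon = lon_c, lat = lat_c)
  keep <- .points_in_polygon(cand$lon, cand$lat, polygon)
  cand <- cand[keep, , drop = FALSE]

  if (!is.null(bathy) && nrow(cand)) {
    floor_depth <- .bathy_at(bathy, cand$lon, cand$lat)
    ocean <- is.finite(floor_depth)
    if (identical(release_depth, "bottom")) {
      cand <- cand[ocean, , drop = FALSE]
      depth <- floor_depth[ocean]
    } else {
      deep_enough <- ocean & floor_depth >= release_depth
      cand <- cand[deep_enough, , drop = FALSE]
      depth <- rep(as.numeric(release_depth), nrow(cand))
    }
  } else {
    if (identical(release_depth, "bottom")) {
      .stop_validation("release_depth = \"bottom\" requires a bathymetry")
    }
    depth <- rep(as.numeric(release_depth), nrow(cand))
  }

  if (nrow(cand) == 0) {
    warn("no seed positions survive the polygon/depth screen",
         class = "capdrift_warning_empty_seed")
  }
  tibble(
    particle_id = seq_len(nrow(cand)),
    lon = cand$lon, lat = cand$lat, depth = depth,
    area_id = rep(as.integer(area_id), nrow(cand))
  )
}

#' Seed particles uniformly over a rectangular domain
#'
#' [seed_polygon()] with the domain box as the polygon.
#'
#' @param domain_box `(lon_min, lon_max, lat_min, lat_max)`.
#' @inheritParams seed_polygon
#' @return Seed tibble as in [seed_polygon()].
#' @export
seed_domain <- function(domain_box, spacing, release_depth, bathy = NULL) {
  b <- as.numeric(domain_box)
  poly <- cbind(lon = c(b[1], b[2], b[2], b[1]),
                lat = c(b[3], b[3], b[4], b[4]))
  seed_polygon(poly, spacing, release_depth, bathy)
}

#' Seed every area of a closed-area set
#'
#' Applies [seed_polygon()] to each area and binds the results with unique
#' particle ids and the source `area_id` attached. Areas whose seafloor
#' never reaches the release depth contribute no particles (with a
#' warning), mirroring depth-limited closures.
#'
#' @param areas A [closed_area_set()].
#' @inheritParams seed_polygon
#' @return Seed tibble.
#' @export
seed_areas <- function(areas, spacing, release_depth, bathy) {
  out <- purrr::map(seq_len(nrow(areas)), function(i) {
    s <- withCallingHandlers(
      seed_polygon(areas$polygon[[i]], spacing, release_depth, bathy,
                   area_id = areas$area_id[i]),
      capdrift_warning_empty_seed = function(w) invokeRestart("muffleWarning")
    )
    s
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    warn("no area yields seeds at this release depth",
         class = "capdrift_warning_empty_seed")
  }
  out$particle_id <- seq_len(nrow(out))
  out
}
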