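#' Regular 3-D ocean grid
#'
#' Axes of a regular longitude/latitude/depth grid. Longitudes are degrees
#' east (negative west), latitudes degrees north, depths metres below the
#' surface (0 = surface, positive down). All axes must be strictly
#' increasing with at least two points.
#'
#' @param lons,lats,depths Numeric axis vectors.
#' @return An `ocean_grid` object (list with `lons`, `lats`, `depths`).
#' @examples
#' ocean_grid(seq(-46, -44, 0.5), seq(46, 48, 0.5), c(0, 100, 1000))
#' @export
ocean_grid <- function(lons, lats, depths) {
  .check_increasing(lons, "lon")
  .check_increasing(lats, "lat")
  .check_increasing(depths, "depth")
  if (depths[1] < 0) .stop_validation("depths must start at or below the surface (>= 0)")
  if (any(lons < -180 | lons >= 180)) {
    .stop_validation("longitudes must lie in [-180, 180) degrees east")
  }
  structure(
    list(lons = as.numeric(lons), lats = as.numeric(lats), depths = as.numeric(depths)),
    class = "ocean_grid"
  )
}

#' @export
print.ocean_grid <- function(x, ...) {
  cat(sprintf(
    "<ocean_grid> %d x %d x %d  lon [%g, %g]  lat [%g, %g]  depth [%g, %g] m\n",
    length(x$lons), length(x$lats), length(x$depths),
    min(x$lons), max(x$lons), min(x$lats), max(x$lats),
    min(x$depths), max(x$depths)
  ))
  invisible(x)
}

.grid_dims <- function(grid) {
  c(length(grid$lons), length(grid$lats), length(grid$depths))
}

.check_field_array <- function(arr, grid, nt, name, bound = NULL) {
  expected <- c(.grid_dims(grid), nt)
  if (!identical(dim(arr), as.integer(expected))) {
    .stop_validation(
      "array '%s' has dim (%s), expected (%s)",
      name, paste(dim(arr), collapse = ", "), paste(expected, collapse = ", ")
    )
  }
  if (!is.null(bound)) {
    mx <- suppressWarnings(max(abs(arr), na.rm = TRUE))
    if (is.finite(mx) && mx > bound) {
      .stop_validation("array '%s' exceeds sanity bound |%s| <= %g (max %g)",
                       name, name, bound, mx)
    }
  }
  invisible(arr)
}

#' Gridded 3-D velocity field
#'
#' Monthly-climatological (or steady) velocity on a regular lon/lat/depth
#' grid. `u` and `v` are eastward/northward velocity in m/s; `w` is vertical
#' velocity in m/s, *positive up* (so downward motion has `w < 0`). Arrays
#' have dimension `(lon, lat, depth, time)`. Cells on land or below the
#' seabed are masked: they carry `NA` in the arrays and `FALSE` in `wet`.
#'
#' @param grid An [ocean_grid()].
#' @param u,v,w Numeric arrays, dim `(nlon, nlat, ndepth, ntime)`.
#' @param months Integer vector of climatological month indices (1-12) for
#'   the time axis, or `NA` for a steady single-slice field.
#' @param wet Logical array `(nlon, nlat, ndepth)`; `FALSE` marks masked
#'   cells. Defaults to cells where `u` is finite in the first time slice.
#' @return A `flow_field` object.
#' @export
flow_field <- function(grid, u, v, w, months = 1:12, wet = NULL) {
  stopifnot(inherits(grid, "ocean_grid"))
  nt <- if (length(months) == 1 && is.na(months)) 1L else length(months)
  .check_field_array(u, grid, nt, "u", bound = 5)
  .check_field_array(v, grid, nt, "v", bound = 5)
  .check_field_array(w, grid, nt, "w", bound = 0.1)
  if (is.null(wet)) {
    wet <- is.finite(u[, , , 1, drop = FALSE])
    dim(wet) <- .grid_dims(grid)
  }
  if (!identical(dim(wet), as.integer(.grid_dims(grid)))) {
    .stop_validation("wet mask has wrong dimensions")
  }
  # masked cells must carry the NA sentinel, never a silent zero
  for (nm in c("u", "v", "w")) {
    arr <- get(nm)
    arr[rep(!wet, times = nt)] <- NA_real_
    assign(nm, arr)
  }
  structure(
    list(grid = grid, months = months, nt = nt, u = u, v = v, w = w, wet = wet),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  tlab <- if (x$nt == 1) "steady" else sprintf("%d monthly slices", x$nt)
  cat(sprintf("<flow_field> %s on grid %d x %d x %d (%.0f%% wet)\n",
              tlab, length(x$grid$lons), length(x$grid$lats),
              length(x$grid$depths), 100 * mean(x$wet)))
  invisible(x)
}

#' Gridded scalar field (temperature or salinity)
#'
#' Same shape discipline as [flow_field()]. The time axis is either a
#' 12-month climatology or a multi-year monthly series described by the
#' `time` tibble (columns `year`, `month`).
#'
#' @param grid An [ocean_grid()].
#' @param values Numeric array `(nlon, nlat, ndepth, ntime)`.
#' @param variable `"temperature"` (degC) or `"salinity"` (practical scale).
#' @param time Tibble with columns `year` and `month`, one row per time
#'   slice, or `NULL` for a plain 12-month climatology.
#' @param wet Logical mask as in [flow_field()].
#' @return A `scalar_field` object.
#' @export
scalar_field <- function(grid, values, variable = c("temperature", "salinity"),
                         time = NULL, wet = NULL) {
  stopifnot(inherits(grid, "ocean_grid"))
  variable <- arg_match(variable)
  if (is.null(time)) {
    if (dim(values)[4] != 12) {
      .stop_validation("climatological scalar_field needs 12 time slices; pass `time` for other axes")
    }
    time <- tibble(year = NA_integer_, month = 1:12)
  }
  nt <- nrow(time)
  .check_field_array(values, grid, nt, variable)
  rng <- if (variable == "temperature") c(-2, 30) else c(0, 40)
  vr <- suppressWarnings(range(values, na.rm = TRUE))
  if (is.finite(vr[1]) && (vr[1] < rng[1] || vr[2] > rng[2])) {
    .stop_validation("%s values outside physical range [%g, %g]", variable, rng[1], rng[2])
  }
  if (is.null(wet)) {
    wet <- is.finite(values[, , , 1, drop = FALSE])
    dim(wet) <- .grid_dims(grid)
  }
  values[rep(!wet, times = nt)] <- NA_real_
  structure(
    list(grid = grid, time = time, nt = nt, values = values,
         variable = variable, wet = wet),
    class = "scalar_field"
  )
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %s, %d time slices on grid %d x %d x %d\n",
              x$variable, x$nt, length(x$grid$lons), length(x$grid$lats),
              length(x$grid$depths)))
  invisible(x)
}

#' Seafloor depth grid
#'
#' @param lons,lats Strictly increasing axis vectors.
#' @param seafloor_depth Matrix `(nlon, nlat)` of seafloor depth in metres,
#'   positive down; `NA` marks land.
#' @return A `bathymetry` object.
#' @export
bathymetry <- function(lons, lats, seafloor_depth) {
  .check_increasing(lons, "lon")
  .check_increasing(lats, "lat")
  if (!identical(dim(seafloor_depth), c(length(lons), length(lats)))) {
    .stop_validation("seafloor_depth must be a (nlon, nlat) matrix")
  }
  if (any(seafloor_depth <= 0, na.rm = TRUE)) {
    .stop_validation("seafloor_depth must be > 0 over ocean (NA marks land)")
  }
  structure(
    list(lons = as.numeric(lons), lats = as.numeric(lats),
         seafloor_depth = seafloor_depth),
    class = "bathymetry"
  )
}

#' @export
print.bathymetry <- function(x, ...) {
  cat(sprintf("<bathymetry> %d x %d, depth range [%g, %g] m, %.0f%% ocean\n",
              length(x$lons), length(x$lats),
              min(x$seafloor_depth, na.rm = TRUE),
              max(x$seafloor_depth, na.rm = TRUE),
              100 * mean(is.finite(x$seafloor_depth))))
  invisible(x)
}
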