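# Plain-text serialization of gridded fields and GeoJSON closed areas.
#
# Fields are stored as a single self-describing TSV: '#'-prefixed header
# lines carry the kind, axes and time metadata; the body is a long table of
# grid indices plus values written at full double precision, so a
# write -> read round trip reproduces arrays bit-exactly. Masked cells are
# written as NA (the mask is recoverable from the sentinel).

.FIELD_MAGIC <- "# capdrift field v1"

.header_line <- function(key, x) {
  sprintf("# %s: %s", key, paste(.fmt_num(x), collapse = ","))
}

#' Write a gridded field to a plain-text file
#'
#' Serializes a [flow_field()], [scalar_field()] or [bathymetry()] object to
#' a self-describing tab-separated text file with commented header lines for
#' the axes, units and time coordinates. The inverse of [read_field()];
#' round trips are bit exact.
#'
#' @param field The field object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (!is.character(path) || length(path) != 1 || !nzchar(path)) {
    .stop_io("invalid output path")
  }
  con <- tryCatch(file(path, "w"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) .stop_io("cannot open '%s' for writing", path)
  on.exit(close(con))

  hdr <- .FIELD_MAGIC
  if (inherits(field, "bathymetry")) {
    hdr <- c(hdr, "# kind: bathymetry",
             .header_line("lons", field$lons), .header_line("lats", field$lats),
             "# units: m")
    nx <- length(field$lons)
    idx <- expand.grid(ix = seq_len(nx), iy = seq_along(field$lats))
    body <- data.frame(idx, seafloor_depth = .fmt_num(as.vector(field$seafloor_depth)))
  } else if (inherits(field, "flow_field")) {
    hdr <- c(hdr, "# kind: flow",
             .header_line("lons", field$grid$lons),
             .header_line("lats", field$grid$lats),
             .header_line("depths", field$grid$depths),
             .header_line("months", field$months),
             "# units: m s-1")
    dm <- c(.grid_dims(field$grid), field$nt)
    idx <- expand.grid(ix = seq_len(dm[1]), iy = seq_len(dm[2]),
                       iz = seq_len(dm[3]), it = seq_len(dm[4]))
    body <- data.frame(idx, u = .fmt_num(as.vector(field$u)),
                       v = .fmt_num(as.vector(field$v)),
                       w = .fmt_num(as.vector(field$w)))
  } else if (inherits(field, "scalar_field")) {
    hdr <- c(hdr, "# kind: scalar",
             sprintf("# variable: %s", field$variable),
             .header_line("lons", field$grid$lons),
             .header_line("lats", field$grid$lats),
             .header_line("depths", field$grid$depths),
             .header_line("years", field$time$year),
             .header_line("time_months", field$time$month),
             sprintf("# units: %s", if (field$variable == "temperature") "degC" else "psu"))
    dm <- c(.grid_dims(field$grid), field$nt)
    idx <- expand.grid(ix = seq_len(dm[1]), iy = seq_len(dm[2]),
                       iz = seq_len(dm[3]), it = seq_len(dm[4]))
    body <- data.frame(idx, value = .fmt_num(as.vector(field$values)))
  } else {
    .stop_validation("unsupported field class: %s", paste(class(field), collapse = "/"))
  }
  writeLines(hdr, con)
  writeLines(paste(colnames(body), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(body)), sep = "\t")), con)
  invisible(path)
}

.parse_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^# ([a-z_]+): ?(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

.header_numeric <- function(kv, key, path) {
  if (is.null(kv[[key]])) {
    .stop_format("file '%s' lacks required coordinate '%s'", path, key)
  }
  raw <- strsplit(kv[[key]], ",", fixed = TRUE)[[1]]
  out <- suppressWarnings(as.numeric(raw))
  if (any(is.na(out) & raw != "NA")) {
    .stop_format("axis '%s' in '%s' contains non-numeric values", key, path)
  }
  out
}

# reorder data so every axis is ascending; returns permutation per axis
.axis_order <- function(ax, name) {
  if (anyNA(ax)) .stop_format("axis '%s' contains NA", name)
  if (all(diff(ax) > 0)) return(seq_along(ax))
  if (all(diff(ax) < 0)) return(rev(seq_along(ax)))
  .stop_format("axis '%s' is not monotone", name)
}

#' Read a gridded field from a plain-text file
#'
#' Reads files written by [write_field()]. Axes stored in descending order
#' are normalized to ascending with the data reordered consistently.
#'
#' @param path Input file path.
#' @param kind Optional expected kind (`"flow"`, `"scalar"`,
#'   `"bathymetry"`); an error is raised on mismatch.
#' @return A [flow_field()], [scalar_field()] or [bathymetry()] object.
#' @export
read_field <- function(path, kind = NULL) {
  if (!file.exists(path)) .stop_io("file '%s' does not exist", path)
  all_lines <- readLines(path, n = 32L)
  if (!length(all_lines) || all_lines[1] != .FIELD_MAGIC) {
    .stop_format("'%s' is not a capdrift field file", path)
  }
  hdr <- all_lines[startsWith(all_lines, "#")]
  kv <- .parse_header(hdr)
  fkind <- kv$kind
  if (is.null(fkind)) .stop_format("file '%s' lacks a kind header", path)
  if (!is.null(kind) && !identical(kind, fkind)) {
    .stop_format("expected kind '%s' but file '%s' holds '%s'", kind, path, fkind)
  }
  body <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            na.strings = "NA")

  lons <- .header_numeric(kv, "lons", path)
  lats <- .header_numeric(kv, "lats", path)
  ox <- .axis_order(lons, "lon")
  oy <- .axis_order(lats, "lat")

  if (fkind == "bathymetry") {
    mat <- matrix(NA_real_, length(lons), length(lats))
    mat[cbind(body$ix, body$iy)] <- body$seafloor_depth
    return(bathymetry(lons[ox], lats[oy], mat[ox, oy, drop = FALSE]))
  }

  depths <- .header_numeric(kv, "depths", path)
  oz <- .axis_order(depths, "depth")
  grid <- ocean_grid(lons[ox], lats[oy], depths[oz])

  fill <- function(col, nt) {
    arr <- array(NA_real_, c(length(lons), length(lats), length(depths), nt))
    arr[cbind(body$ix, body$iy, body$iz, body$it)] <- col
    arr[ox, oy, oz, , drop = FALSE]
  }

  if (fkind == "flow") {
    months <- .header_numeric(kv, "months", path)
    nt <- if (length(months) == 1 && is.na(months)) 1L else length(months)
    flow_field(grid, fill(body$u, nt), fill(body$v, nt), fill(body$w, nt),
               months = months)
  } else if (fkind == "scalar") {
    years <- .header_numeric(kv, "years", path)
    months <- .header_numeric(kv, "time_months", path)
    time <- tibble(year = as.integer(years), month = as.integer(months))
    scalar_field(grid, fill(body$value, nrow(time)),
                 variable = kv$variable %||% "temperature", time = time)
  } else {
    .stop_format("unknown field kind '%s' in '%s'", fkind, path)
  }
}

#' Write a closed-area set to GeoJSON
#'
#' One `Feature` per area with a `Polygon` geometry and properties
#' `area_id`, `groups`, `min_depth`, `max_depth`.
#'
#' @param areas A [closed_area_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_areas_geojson <- function(areas, path) {
  feats <- purrr::pmap(
    list(areas$area_id, areas$groups, areas$min_depth, areas$max_depth, areas$polygon),
    function(id, grp, dmin, dmax, poly) {
      ring <- rbind(poly, poly[1, , drop = FALSE]) # close the ring
      list(
        type = "Feature",
        properties = list(area_id = id, groups = as.list(grp),
                          min_depth = dmin, max_depth = dmax),
        geometry = list(
          type = "Polygon",
          coordinates = list(lapply(seq_len(nrow(ring)),
                                    function(i) c(ring[i, 1], ring[i, 2])))
        )
      )
    }
  )
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a closed-area set from GeoJSON
#'
#' @param path A GeoJSON `FeatureCollection` with one `Polygon` feature per
#'   area (properties `area_id`, optional `groups`, `min_depth`, `max_depth`).
#' @return A [closed_area_set()].
#' @export
read_areas_geojson <- function(path) {
  if (!file.exists(path)) .stop_io("file '%s' does not exist", path)
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    .stop_format("'%s' is not a GeoJSON FeatureCollection", path)
  }
  rows <- purrr::map(fc$features, function(ft) {
    pr <- ft$properties
    coords <- ft$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex if present
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- poly[-nrow(poly), , drop = FALSE]
    }
    colnames(poly) <- c("lon", "lat")
    tibble(
      area_id = as.integer(pr$area_id),
      groups = list(unlist(pr$groups) %||% character()),
      min_depth = as.numeric(pr$min_depth %||% NA),
      max_depth = as.numeric(pr$max_depth %||% NA),
      polygon = list(poly)
    )
  })
  closed_area_set(bind_rows(rows))
}

#' Write / read release positions as CSV
#'
#' Audit-friendly CSV with columns `particle_id, lon, lat, depth, area_id`.
#'
#' @param seeds Seed tibble from [seed_polygon()] or [seed_areas()].
#' @param path File path.
#' @return `path` (write) or the seed tibble (read).
#' @export
write_seeds <- function(seeds, path) {
  readr::write_csv(seeds, path)
  invisible(path)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    particle_id = readr::col_integer(),
                    lon = readr::col_double(),
                    lat = readr::col_double(),
                    depth = readr::col_double(),
                    area_id = readr::col_integer()
                  ))
}
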