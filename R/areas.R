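#' Closed-area set
#'
#' A set of named horizontal closure polygons with the seafloor depth range
#' each contains and the conservation group(s) it belongs to. Stored as a
#' tibble with one row per area and a list-column of `(lon, lat)` vertex
#' matrices (open rings, vertices in order, non-self-intersecting).
#'
#' @param x A tibble with columns `area_id` (integer), `groups`
#'   (list of character vectors), `min_depth`, `max_depth` (m), `polygon`
#'   (list of 2-column matrices `lon`, `lat`).
#' @return A `closed_area_set` (tibble subclass).
#' @export
closed_area_set <- function(x) {
  x <- as_tibble(x)
  need <- c("area_id", "groups", "min_depth", "max_depth", "polygon")
  miss <- setdiff(need, names(x))
  if (length(miss)) .stop_validation("closed_area_set lacks columns: %s",
                                     paste(miss, collapse = ", "))
  if (anyDuplicated(x$area_id)) .stop_validation("area ids must be unique")
  for (i in seq_len(nrow(x))) {
    poly <- x$polygon[[i]]
    if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3) {
      .stop_validation("polygon of area %s needs >= 3 (lon, lat) vertices", x$area_id[i])
    }
    if (!is.na(x$min_depth[i]) && !is.na(x$max_depth[i]) &&
        x$min_depth[i] >= x$max_depth[i]) {
      .stop_validation("area %s: min_depth must be < max_depth", x$area_id[i])
    }
  }
  class(x) <- c("closed_area_set", class(x))
  x
}

#' @export
print.closed_area_set <- function(x, ...) {
  cat(sprintf("<closed_area_set> %d areas (ids %s)\n", nrow(x),
              paste(range(x$area_id), collapse = "-")))
  NextMethod()
}

#' Subset a closed-area set by conservation group
#'
#' @param areas A [closed_area_set()].
#' @param group Group label, e.g. `"sponge"`, `"sea_pen"`, `"gorgonian"`.
#' @return The subset `closed_area_set`.
#' @export
areas_in_group <- function(areas, group) {
  keep <- purrr::map_lgl(areas$groups, ~ group %in% .x)
  closed_area_set(areas[keep, ])
}

# vectorized point-in-polygon (strict interior unless `boundary = TRUE`)
.points_in_polygon <- function(lon, lat, poly, boundary = FALSE) {
  code <- sp::point.in.polygon(lon, lat, poly[, 1], poly[, 2])
  if (boundary) code > 0 else code == 1
}
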