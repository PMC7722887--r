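# ggplot2 autoplot() methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a connectivity matrix
#'
#' @param object A [connectivity_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot connectivity_matrix
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$receiving_area), y = factor(.data$source_area),
    fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$count > 0, sprintf("%.1f", .data$percent), "")
    ), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "receiving area", y = "source area",
                  fill = "% released") +
    ggplot2::theme_minimal()
}

#' Transit-time distributions per receiving area
#'
#' @param object A [transit_time_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transit_time_distribution
#' @export
autoplot.transit_time_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$proportion)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::facet_wrap(~area_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "arrival time (days)", y = "proportion of arrivals") +
    ggplot2::theme_minimal()
}

#' Map of a source-density grid
#'
#' @param object A [source_density_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot source_density_map
#' @export
autoplot.source_density_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$lon_bin, y = .data$lat_bin, fill = .data$proportion
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  fill = "proportion\nof released") +
    ggplot2::theme_minimal()
}

#' Trajectory fan plot
#'
#' @param object A `trajectory_set`.
#' @param max_particles Thin to at most this many particles.
#' @param ... Unused.
#' @return A ggplot of horizontal tracks coloured by depth.
#' @method autoplot trajectory_set
#' @export
autoplot.trajectory_set <- function(object, max_particles = 200, ...) {
  st <- object$states
  ids <- unique(st$particle_id)
  if (length(ids) > max_particles) {
    keep <- ids[seq(1, length(ids), length.out = max_particles)]
    st <- st |> filter(.data$particle_id %in% keep)
  }
  ggplot2::ggplot(st, ggplot2::aes(
    x = .data$lon, y = .data$lat,
    group = .data$particle_id, colour = .data$depth
  )) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = "depth (m)") +
    ggplot2::theme_minimal()
}

#' Bathymetry contour plot with optional closed areas
#'
#' @param bathy A [bathymetry()].
#' @param areas Optional [closed_area_set()] overlay.
#' @return A ggplot.
#' @export
plot_bathymetry <- function(bathy, areas = NULL) {
  df <- expand.grid(lon = bathy$lons, lat = bathy$lats)
  df$depth <- as.vector(bathy$seafloor_depth)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$depth, colour = ggplot2::after_stat(level)),
                          bins = 12) +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = "isobath (m)") +
    ggplot2::theme_minimal()
  if (!is.null(areas)) {
    polys <- purrr::map2(areas$polygon, areas$area_id, function(poly, id) {
      tibble(lon = poly[, 1], lat = poly[, 2], area_id = id)
    }) |> bind_rows()
    p <- p + ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(group = .data$area_id),
      fill = NA, colour = "black", linewidth = 0.4
    )
  }
  p
}
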