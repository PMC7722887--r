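# broom-style tidy()/glance() methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a connectivity matrix into long format
#'
#' @param x A [connectivity_matrix()].
#' @param ... Unused.
#' @return Tibble: `source_area`, `receiving_area`, `count`, `percent`,
#'   `released`, `retention` (logical diagonal flag).
#' @method tidy connectivity_matrix
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  ids <- as.integer(rownames(x$percent))
  grid_df <- expand.grid(source_area = ids, receiving_area = ids)
  tibble(
    source_area = grid_df$source_area,
    receiving_area = grid_df$receiving_area,
    count = as.vector(x$counts),
    percent = as.vector(x$percent),
    released = x$released[as.character(grid_df$source_area)],
    retention = grid_df$source_area == grid_df$receiving_area
  )
}

#' @rdname tidy.connectivity_matrix
#' @method glance connectivity_matrix
#' @export
glance.connectivity_matrix <- function(x, ...) {
  off <- x$percent
  diag(off) <- NA
  tibble(
    n_areas = nrow(x$percent),
    n_released = sum(x$released),
    n_connections = sum(x$counts > 0 & row(x$counts) != col(x$counts)),
    max_percent = suppressWarnings(max(off, na.rm = TRUE)),
    total_retention = sum(diag(x$counts))
  )
}

#' Tidy a trajectory set
#'
#' @param x A `trajectory_set` from [track_particles()].
#' @param ... Unused.
#' @return The long tibble of recorded particle states.
#' @method tidy trajectory_set
#' @export
tidy.trajectory_set <- function(x, ...) {
  x$states
}

#' @rdname tidy.trajectory_set
#' @method glance trajectory_set
#' @export
glance.trajectory_set <- function(x, ...) {
  p <- x$particles
  tibble(
    n_particles = nrow(p),
    n_active = sum(p$status == "active"),
    n_removed_boundary = sum(p$status == "removed_boundary"),
    n_grounded = sum(p$status == "grounded"),
    duration_days = x$config$duration_days,
    dt = x$config$dt,
    K_h = x$config$K_h,
    direction = x$config$direction
  )
}

#' Tidy a visit table
#'
#' @param x A `visit_table` from [detect_visits()].
#' @param ... Unused.
#' @return Tibble of first arrivals joined with source/terminal areas.
#' @method tidy visit_table
#' @export
tidy.visit_table <- function(x, ...) {
  left_join(x$visits, x$particles, by = "particle_id")
}
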