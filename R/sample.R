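# Space-time interpolation of gridded fields.
#
# Trilinear in (lon, lat, depth); linear in time between adjacent
# climatological months with a December -> January wrap. Masked corner cells
# are excluded and the remaining weights renormalized, which avoids
# artificially damping velocities against the seabed. A point whose eight
# spatial neighbours are all masked yields a "grounded" signal; a point
# outside the horizontal grid box yields an "out_of_domain" signal. Depth is
# clamped to the grid's vertical range (constant extrapolation).

.axis_locate <- function(x, ax) {
  i <- findInterval(x, ax, rightmost.closed = TRUE, all.inside = TRUE)
  f <- (x - ax[i]) / (ax[i + 1L] - ax[i])
  f[!is.finite(f)] <- 0
  list(i = i, f = pmin(pmax(f, 0), 1))
}

# Time weights for a climatological monthly axis: slice m is valid at the
# month centre m - 0.5, so time_of_year = 11.9 blends December and January.
.month_weights <- function(time_of_year, nt) {
  if (nt == 1L) {
    return(list(t1 = 1L, t2 = 1L, w1 = 1, w2 = 0))
  }
  tm <- (time_of_year - 0.5) %% 12
  i1 <- floor(tm)
  f <- tm - i1
  t1 <- (as.integer(i1) %% 12L) + 1L
  t2 <- (t1 %% 12L) + 1L
  list(t1 = t1, t2 = t2, w1 = 1 - f, w2 = f)
}

# Multi-year monthly axis: continuous time in months since the series start,
# slice i centred at i - 0.5, clamped at the ends (no wrap).
.series_weights <- function(time_months, nt) {
  tm <- pmin(pmax(time_months - 0.5, 0), nt - 1)
  i1 <- pmin(floor(tm), nt - 2)
  f <- tm - i1
  list(t1 = as.integer(i1) + 1L, t2 = as.integer(i1) + 2L, w1 = 1 - f, w2 = f)
}

# Core kernel. `arrays` is a named list of (nx, ny, nz, nt) arrays sharing
# `grid` and `wet`; returns list(values = named list, status = int vector).
.interp_field <- function(arrays, grid, wet, lon, lat, depth, tw) {
  nx <- length(grid$lons)
  ny <- length(grid$lats)
  nz <- length(grid$depths)
  n <- length(lon)

  oob <- !is.finite(lon) | !is.finite(lat) |
    lon < grid$lons[1] | lon > grid$lons[nx] |
    lat < grid$lats[1] | lat > grid$lats[ny]

  lx <- .axis_locate(lon, grid$lons)
  ly <- .axis_locate(lat, grid$lats)
  lz <- .axis_locate(depth, grid$depths)

  wsum <- numeric(n)
  nvar <- length(arrays)
  acc1 <- vector("list", nvar) # time slice 1 accumulators
  acc2 <- vector("list", nvar)
  for (v in seq_len(nvar)) {
    acc1[[v]] <- numeric(n)
    acc2[[v]] <- numeric(n)
  }
  two_slices <- any(tw$w2 > 0)
  off1 <- (tw$t1 - 1L) * (nx * ny * nz)
  off2 <- (tw$t2 - 1L) * (nx * ny * nz)

  for (a in 0:1) {
    wx <- if (a == 0) 1 - lx$f else lx$f
    ii <- lx$i + a
    for (b in 0:1) {
      wy <- if (b == 0) 1 - ly$f else ly$f
      jj <- ly$i + b
      for (cc in 0:1) {
        wz <- if (cc == 0) 1 - lz$f else lz$f
        kk <- lz$i + cc
        lin <- ii + nx * ((jj - 1L) + ny * (kk - 1L))
        wcell <- wx * wy * wz * as.numeric(wet[lin])
        wsum <- wsum + wcell
        for (v in seq_len(nvar)) {
          a1 <- arrays[[v]][lin + off1]
          a1[is.na(a1)] <- 0
          acc1[[v]] <- acc1[[v]] + wcell * a1
          if (two_slices) {
            a2 <- arrays[[v]][lin + off2]
            a2[is.na(a2)] <- 0
            acc2[[v]] <- acc2[[v]] + wcell * a2
          }
        }
      }
    }
  }

  status <- rep(STATUS_OK, n)
  status[wsum <= 0] <- STATUS_GROUNDED
  status[oob] <- STATUS_OUT_OF_DOMAIN
  bad <- status != STATUS_OK
  wsum[wsum <= 0] <- NA_real_

  values <- vector("list", nvar)
  names(values) <- names(arrays)
  for (v in seq_len(nvar)) {
    val <- if (two_slices) {
      (tw$w1 * acc1[[v]] + tw$w2 * acc2[[v]]) / wsum
    } else {
      acc1[[v]] / wsum
    }
    val[bad] <- NA_real_
    values[[v]] <- val
  }
  list(values = values, status = status)
}

# internal fast path used by the tracker
.velocity_at <- function(field, lon, lat, depth, time_of_year) {
  UseMethod(".velocity_at")
}

#' @export
.velocity_at.flow_field <- function(field, lon, lat, depth, time_of_year) {
  tw <- .month_weights(time_of_year, field$nt)
  out <- .interp_field(list(u = field$u, v = field$v, w = field$w),
                       field$grid, field$wet, lon, lat, depth, tw)
  list(u = out$values$u, v = out$values$v, w = out$values$w, status = out$status)
}

#' Sample velocity at arbitrary points
#'
#' Interpolates a [flow_field()] trilinearly in space and linearly in
#' climatological time (December wraps to January). Masked neighbours are
#' dropped with weight renormalization; a fully-masked neighbourhood returns
#' status `"grounded"`, a point outside the horizontal grid box
#' `"out_of_domain"` (velocities `NA` in both cases).
#'
#' @param field A [flow_field()] or analytic flow from [make_analytic_flow()].
#' @param lon,lat,depth Numeric vectors of positions (depth metres, positive
#'   down; clamped to the grid's vertical range).
#' @param time_of_year Fractional month in `[0, 12)`; ignored for steady
#'   fields.
#' @return A tibble with columns `u`, `v`, `w` (m/s; `w` positive up) and
#'   `status` (`"ok"`, `"out_of_domain"`, `"grounded"`).
#' @export
sample_velocity <- function(field, lon, lat, depth, time_of_year = 0) {
  s <- .velocity_at(field, lon, lat, depth, time_of_year)
  tibble(u = s$u, v = s$v, w = s$w, status = .status_label(s$status))
}

#' Sample a scalar field at arbitrary points
#'
#' Same kernel as [sample_velocity()]. For multi-year series, `time` is the
#' continuous month index since the series start (no wrap); for 12-month
#' climatologies it is the fractional month of year with wrap.
#'
#' @param field A [scalar_field()].
#' @param lon,lat,depth Positions.
#' @param time Time coordinate (see Details).
#' @return A tibble with columns `value` and `status`.
#' @export
sample_scalar <- function(field, lon, lat, depth, time = 0) {
  tw <- if (field$nt == 12 && all(is.na(field$time$year))) {
    .month_weights(time, field$nt)
  } else if (field$nt == 1) {
    .month_weights(time, 1L)
  } else {
    .series_weights(time, field$nt)
  }
  out <- .interp_field(list(value = field$values), field$grid, field$wet,
                       lon, lat, depth, tw)
  tibble(value = out$values$value, status = .status_label(out$status))
}

#' Bottom value of a scalar field
#'
#' Value at the deepest unmasked level of the grid column nearest to each
#' point (no vertical extrapolation). A fully-masked (land) column returns
#' status `"grounded"`.
#'
#' @inheritParams sample_scalar
#' @return A tibble with columns `value`, `bottom_depth`, `status`.
#' @export
bottom_value <- function(field, lon, lat, time = 0) {
  grid <- field$grid
  nx <- length(grid$lons)
  ny <- length(grid$lats)
  i <- .nearest_index(lon, grid$lons)
  j <- .nearest_index(lat, grid$lats)
  oob <- lon < grid$lons[1] | lon > grid$lons[nx] |
    lat < grid$lats[1] | lat > grid$lats[ny]

  kbot <- .column_bottom_index(field$wet)
  kb <- kbot[cbind(i, j)]
  tw <- if (field$nt == 12 && all(is.na(field$time$year))) {
    .month_weights(time, field$nt)
  } else if (field$nt == 1) {
    .month_weights(time, 1L)
  } else {
    .series_weights(time, field$nt)
  }
  n <- length(lon)
  val <- rep(NA_real_, n)
  ok <- kb > 0 & !oob
  if (any(ok)) {
    lin <- i[ok] + nx * ((j[ok] - 1L) + ny * (kb[ok] - 1L))
    sz <- nx * ny * length(grid$depths)
    v1 <- field$values[lin + (tw$t1 - 1L) * sz]
    v2 <- field$values[lin + (tw$t2 - 1L) * sz]
    val[ok] <- tw$w1 * v1 + tw$w2 * v2
  }
  status <- rep(STATUS_OK, n)
  status[kb == 0] <- STATUS_GROUNDED
  status[oob] <- STATUS_OUT_OF_DOMAIN
  bdepth <- rep(NA_real_, n)
  bdepth[ok] <- grid$depths[kb[ok]]
  tibble(value = val, bottom_depth = bdepth, status = .status_label(status))
}

.nearest_index <- function(x, ax) {
  i <- findInterval(x, ax, rightmost.closed = TRUE, all.inside = TRUE)
  i + as.integer(abs(x - ax[i + 1L]) < abs(x - ax[i]))
}

# deepest wet level per column; 0 when the whole column is masked
.column_bottom_index <- function(wet) {
  dm <- dim(wet)
  apply(array(wet, dm), c(1, 2), function(col) {
    w <- which(col)
    if (length(w)) max(w) else 0L
  })
}

# Bilinear seafloor depth with NA-aware renormalization; NA over land.
.bathy_at <- function(bathy, lon, lat) {
  nx <- length(bathy$lons)
  ny <- length(bathy$lats)
  lx <- .axis_locate(lon, bathy$lons)
  ly <- .axis_locate(lat, bathy$lats)
  num <- numeric(length(lon))
  den <- numeric(length(lon))
  for (a in 0:1) {
    wx <- if (a == 0) 1 - lx$f else lx$f
    for (b in 0:1) {
      wy <- if (b == 0) 1 - ly$f else ly$f
      z <- bathy$seafloor_depth[cbind(lx$i + a, ly$i + b)]
      wcell <- wx * wy * as.numeric(is.finite(z))
      z[!is.finite(z)] <- 0
      num <- num + wcell * z
      den <- den + wcell
    }
  }
  out <- num / den
  out[den <= 0] <- NA_real_
  oob <- lon < bathy$lons[1] | lon > bathy$lons[nx] |
    lat < bathy$lats[1] | lat > bathy$lats[ny]
  out[oob] <- NA_real_
  out
}
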