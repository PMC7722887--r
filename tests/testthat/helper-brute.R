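# Independent naive reimplementations of the trajectory statistics, used as
# oracles: plain loops over every particle and step, and a from-scratch
# ray-casting containment test (no shared code with the package internals).

brute_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# first arrivals + terminal areas by explicit loops over states
brute_visits <- function(traj, areas) {
  pids <- traj$particles$particle_id
  res <- list()
  term <- rep(NA_integer_, length(pids))
  for (pi in seq_along(pids)) {
    rows <- traj$states[traj$states$particle_id == pids[pi], ]
    rows <- rows[order(rows$time_s), ]
    rows <- rows[rows$status != "removed_boundary", ]
    for (ai in seq_len(nrow(areas))) {
      poly <- areas$polygon[[ai]]
      hit <- NA_real_
      for (ri in seq_len(nrow(rows))) {
        if (brute_point_in_poly(rows$lon[ri], rows$lat[ri], poly)) {
          hit <- rows$time_s[ri]
          break
        }
      }
      if (!is.na(hit)) {
        res[[length(res) + 1]] <- data.frame(
          particle_id = pids[pi], area_id = areas$area_id[ai],
          first_arrival_s = hit
        )
      }
    }
    if (nrow(rows)) {
      last <- rows[nrow(rows), ]
      for (ai in seq_len(nrow(areas))) {
        if (brute_point_in_poly(last$lon, last$lat, areas$polygon[[ai]])) {
          term[pi] <- areas$area_id[ai]
          break
        }
      }
    }
  }
  list(
    visits = if (length(res)) do.call(rbind, res) else
      data.frame(particle_id = integer(), area_id = integer(),
                 first_arrival_s = numeric()),
    terminal = data.frame(particle_id = pids,
                          source_area_id = traj$particles$area_id,
                          terminal_area_id = term)
  )
}

brute_connectivity <- function(bv, area_ids) {
  k <- length(area_ids)
  counts <- matrix(0, k, k, dimnames = list(source = area_ids, receiver = area_ids))
  released <- numeric(k)
  for (s in seq_len(k)) {
    from_s <- bv$terminal[bv$terminal$source_area_id == area_ids[s], ]
    released[s] <- nrow(from_s)
    for (r in seq_len(k)) {
      if (s == r) {
        counts[s, r] <- sum(!is.na(from_s$terminal_area_id) &
                              from_s$terminal_area_id == area_ids[s])
      } else {
        nvis <- 0
        for (pi in from_s$particle_id) {
          visited <- any(bv$visits$particle_id == pi &
                           bv$visits$area_id == area_ids[r])
          terminated <- !is.na(from_s$terminal_area_id[from_s$particle_id == pi]) &&
            from_s$terminal_area_id[from_s$particle_id == pi] == area_ids[r]
          if (visited || terminated) nvis <- nvis + 1
        }
        counts[s, r] <- nvis
      }
    }
  }
  list(counts = counts, percent = 100 * counts / released, released = released)
}

brute_ttd <- function(bv, bin_width_days = 1) {
  rows <- merge(bv$visits, bv$terminal, by = "particle_id")
  rows <- rows[is.na(rows$source_area_id) | rows$area_id != rows$source_area_id, ]
  if (!nrow(rows)) return(data.frame(area_id = integer(), day = numeric(),
                                     proportion = numeric()))
  rows$day <- floor(rows$first_arrival_s / 86400 / bin_width_days) * bin_width_days
  out <- list()
  for (a in sort(unique(rows$area_id))) {
    sub <- rows[rows$area_id == a, ]
    tab <- table(sub$day)
    out[[length(out) + 1]] <- data.frame(
      area_id = a, day = as.numeric(names(tab)),
      n = as.integer(tab), proportion = as.integer(tab) / nrow(sub)
    )
  }
  do.call(rbind, out)
}

brute_source_map <- function(traj, bv, bin = 0.1) {
  qual <- union(bv$visits$particle_id,
                bv$terminal$particle_id[!is.na(bv$terminal$terminal_area_id)])
  p <- traj$particles[traj$particles$particle_id %in% qual, ]
  if (!nrow(p)) return(data.frame(lon_bin = numeric(), lat_bin = numeric(),
                                  count = integer()))
  key <- paste(floor(p$release_lon / bin), floor(p$release_lat / bin))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(
    lon_bin = (as.numeric(parts[, 1]) + 0.5) * bin,
    lat_bin = (as.numeric(parts[, 2]) + 0.5) * bin,
    count = as.integer(tab)
  )
  out[order(out$lon_bin, out$lat_bin), ]
}

# percentile by explicit sort + linear interpolation (median-style, type 7)
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

brute_vertical <- function(particles, percentiles = c(25, 50, 75)) {
  out <- list(min_depth_reached = min(particles$min_depth),
              max_depth_reached = max(particles$max_depth))
  for (p in percentiles) {
    out[[sprintf("max_p%d", p)]] <- brute_percentile(particles$max_depth, p / 100)
    out[[sprintf("min_p%d", p)]] <- brute_percentile(particles$min_depth, 1 - p / 100)
  }
  out
}

# a reproducible 50-particle random-walk fixture across the three squares
brute_fixture_traj <- function(n = 50, nsteps = 20, seed = 99) {
  set.seed(seed)
  areas <- three_square_areas()
  src <- sample(areas$area_id, n, replace = TRUE)
  lon0 <- -45.5 + (src - 1) * 1 + rnorm(n, 0, 0.1)
  lon0[src == 3] <- -45.0 + rnorm(sum(src == 3), 0, 0.1)
  lat0 <- ifelse(src == 3, 47.5, 46.5) + rnorm(n, 0, 0.1)
  dep0 <- runif(n, 50, 500)
  lon <- lon0; lat <- lat0; dep <- dep0
  states <- list(data.frame(particle_id = 1:n, obs = 0L, time_s = 0,
                            lon = lon, lat = lat, depth = dep,
                            status = "active"))
  for (s in seq_len(nsteps)) {
    lon <- lon + rnorm(n, 0.02, 0.15)
    lat <- lat + rnorm(n, 0.01, 0.15)
    dep <- pmax(dep + rnorm(n, 5, 40), 0)
    states[[s + 1]] <- data.frame(particle_id = 1:n, obs = s,
                                  time_s = s * 43200, lon = lon, lat = lat,
                                  depth = dep, status = "active")
  }
  st <- dplyr::bind_rows(states)
  mins <- stats::aggregate(depth ~ particle_id, st, min)$depth
  maxs <- stats::aggregate(depth ~ particle_id, st, max)$depth
  particles <- tibble::tibble(
    particle_id = 1:n, area_id = src,
    release_lon = lon0, release_lat = lat0, release_depth = dep0,
    final_lon = lon, final_lat = lat, final_depth = dep,
    min_depth = mins, max_depth = maxs, status = "active"
  )
  manual_traj(tibble::as_tibble(st), particles, dt = 43200)
}
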