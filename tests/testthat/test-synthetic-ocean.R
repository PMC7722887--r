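# Synthetic cap ocean: bathymetry, circulation, oracle flows, T/S, areas.

test_that("seamount bathymetry follows the Gaussian relief", {
  params <- fix_params()
  b <- fix_bathy()
  # depth at the centre equals the summit depth
  centre <- .bathy_at(b, params$center_lon, params$center_lat)
  expect_equal(centre, params$summit_depth, tolerance = 1e-6)

  # at r >= 3R the relief reaches the abyssal depth within 1%
  kx <- pi * 6371000 / 180 * cos(params$center_lat * pi / 180)
  r3 <- 3 * params$cap_radius_km * 1000
  lat_r3 <- params$center_lat - r3 / (pi * 6371000 / 180)
  far <- .bathy_at(b, params$center_lon, lat_r3)
  expect_lt(abs(far - params$abyss_depth) / params$abyss_depth, 0.01)

  # monotone along a radial transect
  lons <- seq(params$center_lon, params$center_lon + 3, by = 0.05)
  z <- .bathy_at(b, lons, rep(params$center_lat, length(lons)))
  expect_true(all(diff(z) >= -1e-9))
})

test_that("cap circulation is clockwise, slope-following and non-divergent", {
  params <- fix_params()
  flow <- fix_flow_steady()

  # near-zero horizontal speed over the flat summit
  s0 <- sample_velocity(flow, params$center_lon, params$center_lat, 50, 0)
  expect_lt(sqrt(s0$u^2 + s0$v^2), 1e-3)

  # clockwise: at a point due east of the centre the flow runs south
  kx <- pi * 6371000 / 180 * cos(params$center_lat * pi / 180)
  rj <- .cap_isobath_radius(params, params$jet_core_isobath_m)
  east <- params$center_lon + rj / kx
  sj <- sample_velocity(flow, east, params$center_lat, 500, 0)
  expect_lt(sj$v, 0)
  expect_equal(sqrt(sj$u^2 + sj$v^2), params$jet_peak_speed, tolerance = 0.05)

  # w is downward on the upper slope, upward offshore, zero in the surface layer
  r_dn <- .cap_isobath_radius(params, params$downwelling_isobath_m)
  r_up <- .cap_isobath_radius(params, params$upwelling_isobath_m)
  w_dn <- sample_velocity(flow, params$center_lon + r_dn / kx, params$center_lat, 500, 0)$w
  w_up <- sample_velocity(flow, params$center_lon + r_up / kx, params$center_lat, 1000, 0)$w
  w_sf <- sample_velocity(flow, params$center_lon + r_dn / kx, params$center_lat, 10, 0)$w
  expect_lt(w_dn, 0)
  expect_gt(w_up, 0)
  expect_equal(w_sf, 0)

  # discrete horizontal divergence vanishes within finite-difference error
  u <- flow$u[, , 8, 1]; v <- flow$v[, , 8, 1]
  lons <- flow$grid$lons; lats <- flow$grid$lats
  dx <- diff(lons)[1] * pi / 180 * 6371000 * cos(params$center_lat * pi / 180)
  dy <- diff(lats)[1] * pi / 180 * 6371000
  nx <- length(lons); ny <- length(lats)
  div <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * dx) +
    (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) / (2 * dy)
  # O(dx^2) error scale: a few percent of U / L with L ~ jet width
  expect_lt(max(abs(div), na.rm = TRUE), 1e-6)

  expect_error(
    make_cap_circulation(fix_bathy(), cap_params(jet_core_isobath_m = 5000)),
    class = "capdrift_error_validation"
  )
})

test_that("seasonal modulation strengthens summer/autumn slices everywhere on the slope", {
  flow <- fix_flow_monthly()
  w_jul <- flow$w[, , 8, 7]
  w_jan <- flow$w[, , 8, 1]
  sel <- !is.na(w_jul) & abs(w_jul) > 1e-8
  expect_true(all(abs(w_jul[sel]) > abs(w_jan[sel])))
})

test_that("analytic oracle flows evaluate their closed forms", {
  z <- make_analytic_flow("zero")
  s <- sample_velocity(z, -45, 47, 100, 3)
  expect_equal(c(s$u, s$v, s$w), c(0, 0, 0))

  u <- make_analytic_flow("uniform", list(u0 = 0.1))
  su <- sample_velocity(u, c(-45, -50), c(47, 42), c(0, 800), 0)
  expect_equal(su$u, c(0.1, 0.1))
  expect_equal(su$v, c(0, 0))

  # solid rotation: speed omega * r at 10 km radius
  sr <- make_analytic_flow("solid_rotation",
                           list(omega = 1e-4, center_lon = -45, center_lat = 0))
  kx <- pi * 6371000 / 180
  ssr <- sample_velocity(sr, -45 + 10000 / kx, 0, 0, 0)
  expect_equal(sqrt(ssr$u^2 + ssr$v^2), 1.0, tolerance = 1e-9)

  expect_error(make_analytic_flow("vortex"))
})

test_that("synthetic bottom water is cold and salty at depth, deterministically", {
  params <- fix_params()
  b <- fix_bathy()
  ts1 <- make_ts_climatology(b, params, seed = 4)
  # a slope column with ~1400 m of water
  kx <- pi * 6371000 / 180 * cos(params$center_lat * pi / 180)
  r14 <- .cap_isobath_radius(params, 1400)
  lon14 <- params$center_lon + r14 / kx
  bt <- bottom_value(ts1$temperature, lon14, params$center_lat, 0)
  bs <- bottom_value(ts1$salinity, lon14, params$center_lat, 0)
  expect_lt(bt$value, 4)
  expect_gt(bs$value, 34.8)

  ts2 <- make_ts_climatology(b, params, seed = 4)
  expect_identical(ts1$temperature$values, ts2$temperature$values)
})

test_that("the fixture closure set has 14 labelled areas on the ocean", {
  areas <- fix_areas()
  expect_equal(sort(areas$area_id), 1:14)
  sponge <- areas_in_group(areas, "sponge")
  expect_equal(sort(sponge$area_id), 1:6)
  expect_setequal(areas_in_group(areas, "sea_pen")$area_id, c(2, 7:12, 14))
  expect_setequal(areas_in_group(areas, "gorgonian")$area_id, c(2, 4, 5, 13))

  b <- fix_bathy()
  for (i in seq_len(nrow(areas))) {
    z <- .bathy_at(b, areas$polygon[[i]][, 1], areas$polygon[[i]][, 2])
    expect_true(all(is.finite(z)))
  }

  # pairwise non-overlapping: no vertex of one polygon inside another
  for (i in 1:13) for (j in (i + 1):14) {
    pi_ <- areas$polygon[[i]]; pj <- areas$polygon[[j]]
    expect_false(any(.points_in_polygon(pi_[, 1], pi_[, 2], pj)),
                 info = sprintf("areas %d vs %d", i, j))
  }
})

test_that("areas round-trip through GeoJSON", {
  areas <- fix_areas()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_areas_geojson(areas, path)
  back <- read_areas_geojson(path)
  expect_equal(back$area_id, areas$area_id)
  expect_equal(back$min_depth, areas$min_depth)
  expect_equal(back$polygon[[4]], areas$polygon[[4]], tolerance = 1e-12)
  expect_setequal(back$groups[[2]], areas$groups[[2]])
})

test_that("non-diffusive drift in the cap flow stays in a bounded isobath band", {
  params <- fix_params()
  b <- fix_bathy()
  flow <- fix_flow_steady()
  ann <- isobath_annulus(params, 900, 1800)
  set.seed(2)
  seeds <- seed_polygon(ann, 0.05, 500, b)
  seeds <- seeds[sample(nrow(seeds), 12), ]
  seeds$particle_id <- seq_len(nrow(seeds))
  cfg <- tracker_config(K_h = 0, duration_days = 30, record_every = 72,
                        domain_box = cap_domain_box())
  tr <- track_particles(seeds, flow, cfg, bathy = b)
  h0 <- rep(.cap_depth(params, seeds$lon, seeds$lat),
            times = length(unique(tr$states$obs)))
  h <- .cap_depth(params, tr$states$lon, tr$states$lat)
  expect_lt(max(abs(h - h0) / h0), 0.10)
})

test_that("upper-slope releases drift downward on median (sign test)", {
  params <- fix_params()
  b <- fix_bathy()
  flow <- fix_flow_steady()
  ann <- isobath_annulus(params, 1000, 1600)
  set.seed(3)
  seeds <- seed_polygon(ann, 0.04, 450, b)
  seeds <- seeds[sample(nrow(seeds), 60), ]
  seeds$particle_id <- seq_len(nrow(seeds))
  cfg <- tracker_config(K_h = 100, duration_days = 7, seed = 8,
                        record_every = 1000L, domain_box = cap_domain_box())
  tr <- track_particles(seeds, flow, cfg, bathy = b)
  dz <- tr$particles$final_depth - tr$particles$release_depth
  expect_gt(median(dz), 0)
  pv <- stats::binom.test(sum(dz > 0), length(dz))$p.value
  expect_lt(pv, 0.01)
})
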