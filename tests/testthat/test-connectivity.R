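# Visit detection, connectivity matrices, TTDs, source maps, vertical stats.

test_that("visits record first arrivals, terminals and retention candidates", {
  areas <- three_square_areas()
  # particle 1 crosses area 2 at step 3 (time 3 * 43200 s) and ends outside;
  # particle 2 never enters a polygon; particle 3 stays in its release area
  st <- tibble::tibble(
    particle_id = rep(1:3, each = 4),
    obs = rep(0:3, 3),
    time_s = rep((0:3) * 43200, 3),
    lon = c(-45.5, -45.2, -44.9, -44.5,   # p1: from area 1 into area 2
            -46.9, -46.9, -46.9, -46.9,   # p2: far away
            -45.0, -45.05, -44.95, -45.0),# p3: inside area 3 throughout
    lat = c(46.5, 46.5, 46.5, 46.5,
            47.9, 47.9, 47.9, 47.9,
            47.5, 47.5, 47.5, 47.5),
    depth = 100, status = "active"
  )
  pt <- tibble::tibble(
    particle_id = 1:3, area_id = c(1L, 1L, 3L),
    release_lon = c(-45.5, -46.9, -45.0), release_lat = c(46.5, 47.9, 47.5),
    release_depth = 100,
    final_lon = c(-44.5, -46.9, -45.0), final_lat = c(46.5, 47.9, 47.5),
    final_depth = 100, min_depth = 100, max_depth = 100, status = "active"
  )
  traj <- manual_traj(st, pt, dt = 43200)
  vt <- detect_visits(traj, areas)

  v1 <- vt$visits[vt$visits$particle_id == 1 & vt$visits$area_id == 2, ]
  expect_equal(v1$first_arrival_s, 3 * 43200)  # first in-polygon step
  expect_false(2 %in% vt$visits$particle_id)   # empty row for the wanderer
  p3 <- vt$particles[vt$particles$particle_id == 3, ]
  expect_equal(p3$terminal_area_id, 3L)        # retention candidate
  expect_equal(p3$source_area_id, 3L)
})

test_that("connectivity percentages, retention diagonal and degenerate rows", {
  areas <- three_square_areas()
  mk_vt <- function(visits, particles) {
    structure(list(visits = visits, particles = particles,
                   area_ids = areas$area_id), class = "visit_table")
  }
  # 4 particles from area 1, two of which visit area 2 -> (1, 2) = 50%
  vt <- mk_vt(
    tibble::tibble(particle_id = c(1L, 2L), area_id = c(2L, 2L),
                   first_arrival_s = c(86400, 172800)),
    tibble::tibble(particle_id = 1:4, source_area_id = 1L,
                   terminal_area_id = NA_integer_)
  )
  cm <- suppressWarnings(connectivity_matrix(vt))
  expect_equal(cm$percent["1", "2"], 50)
  expect_equal(cm$counts["1", "2"], 2)
  expect_true(all(is.na(cm$percent[c("2", "3"), ])))  # zero released -> NA
  expect_warning(connectivity_matrix(vt), class = "capdrift_warning_empty_source")

  # all particles retained -> diagonal 100
  vt2 <- mk_vt(
    tibble::tibble(particle_id = integer(), area_id = integer(),
                   first_arrival_s = numeric()),
    tibble::tibble(particle_id = 1:6,
                   source_area_id = rep(1:3, each = 2),
                   terminal_area_id = rep(1:3, each = 2))
  )
  cm2 <- suppressWarnings(connectivity_matrix(vt2))
  expect_equal(diag(cm2$percent), c("1" = 100, "2" = 100, "3" = 100))
  expect_equal(sum(cm2$counts) - sum(diag(cm2$counts)), 0)

  # no visits at all -> all-zero matrix
  vt3 <- mk_vt(
    tibble::tibble(particle_id = integer(), area_id = integer(),
                   first_arrival_s = numeric()),
    tibble::tibble(particle_id = 1:3, source_area_id = 1:3,
                   terminal_area_id = NA_integer_)
  )
  cm3 <- connectivity_matrix(vt3)
  expect_true(all(cm3$counts == 0))
  expect_true(all(cm3$percent == 0))
})

test_that("transit-time distributions tally arrival days and exclude retention", {
  areas <- three_square_areas()
  vt <- structure(list(
    visits = tibble::tibble(
      particle_id = c(1L, 2L, 3L, 4L),
      area_id = c(2L, 2L, 2L, 1L),
      first_arrival_s = c(2.3, 2.7, 4.1, 0.5) * 86400
    ),
    particles = tibble::tibble(particle_id = 1:4, source_area_id = c(1L, 1L, 1L, 1L),
                               terminal_area_id = c(NA, NA, 2L, 1L)),
    area_ids = areas$area_id
  ), class = "visit_table")
  tt <- transit_time_distribution(vt)
  a2 <- tt[tt$area_id == 2, ]
  expect_equal(a2$day, c(2, 4))
  expect_equal(a2$proportion, c(2 / 3, 1 / 3))
  # the day-0 arrival into area 1 is retention-free here (source 1, area 1
  # is the release area, so it is excluded)
  expect_false(1 %in% tt$area_id)

  # only retained particles -> empty distribution
  vt2 <- vt
  vt2$visits <- vt$visits[4, ]
  expect_equal(nrow(transit_time_distribution(vt2)), 0)

  # single arrival -> one bin of mass 1
  vt3 <- vt
  vt3$visits <- vt$visits[3, ]
  tt3 <- transit_time_distribution(vt3)
  expect_equal(tt3$proportion, 1)
  expect_equal(sum(tt3$proportion), 1)
})

test_that("source-density maps bin initial positions on a 0.1 degree grid", {
  areas <- three_square_areas()
  # two qualifying particles in one 0.1 x 0.1 cell, one non-qualifying
  st <- tibble::tibble(
    particle_id = rep(1:3, each = 2), obs = rep(0:1, 3),
    time_s = rep(c(0, 43200), 3),
    lon = c(-45.01, -44.5, -45.05, -44.5, -46.9, -46.9),
    lat = c(47.02, 46.5, 47.08, 46.5, 47.9, 47.9),
    depth = 100, status = "active"
  )
  pt <- tibble::tibble(
    particle_id = 1:3, area_id = NA_integer_,
    release_lon = c(-45.01, -45.05, -46.9), release_lat = c(47.02, 47.08, 47.9),
    release_depth = 100,
    final_lon = c(-44.5, -44.5, -46.9), final_lat = c(46.5, 46.5, 47.9),
    final_depth = 100, min_depth = 100, max_depth = 100, status = "active"
  )
  traj <- manual_traj(st, pt, dt = 43200)
  sm <- source_density_map(traj, areas)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$count, 2)
  expect_equal(sm$lon_bin, -45.05)
  expect_equal(sm$lat_bin, 47.05)
  expect_equal(sm$proportion, 2 / 3)
  expect_equal(sum(sm$count), attr(sm, "n_qualifying"))

  # no qualifying particles -> empty map
  traj2 <- traj
  traj2$states <- traj$states[traj$states$particle_id == 3, ]
  traj2$particles <- traj$particles[3, ]
  expect_equal(nrow(source_density_map(traj2, areas)), 0)
})

test_that("vertical statistics implement percentile-of-extremes", {
  p <- tibble::tibble(
    particle_id = 1:4, area_id = 1L,
    release_lon = 0, release_lat = 0, release_depth = 100,
    final_lon = 0, final_lat = 0, final_depth = 100,
    min_depth = c(90, 80, 100, 100), max_depth = c(110, 120, 130, 900),
    status = "active"
  )
  vs <- vertical_stats(p)
  expect_equal(vs$max_p50, 125)          # median of {110, 120, 130, 900}
  expect_equal(vs$max_depth_reached, 900)
  expect_equal(vs$min_depth_reached, 80)

  # all particles frozen at the release depth -> every statistic 100 m
  pf <- p
  pf$min_depth <- 100; pf$max_depth <- 100
  vsf <- vertical_stats(pf)
  expect_true(all(unlist(vsf[, c("min_depth_reached", "max_depth_reached",
                                 "min_p25", "min_p50", "min_p75",
                                 "max_p25", "max_p50", "max_p75")]) == 100))

  # ordering chains on random inputs, both sides of the release depth
  set.seed(14)
  for (i in 1:5) {
    pr <- p[rep(1, 30), ]
    pr$particle_id <- 1:30
    pr$max_depth <- 100 + stats::rexp(30, 1 / 200)
    pr$min_depth <- pmax(100 - stats::rexp(30, 1 / 50), 0)
    v <- vertical_stats(pr)
    expect_true(v$max_p25 <= v$max_p50 && v$max_p50 <= v$max_p75 &&
                  v$max_p75 <= v$max_depth_reached)
    expect_true(v$min_p25 >= v$min_p50 && v$min_p50 >= v$min_p75 &&
                  v$min_p75 >= v$min_depth_reached)
  }

  expect_warning(vertical_stats(p[1, ]), class = "capdrift_warning_degenerate")
})

test_that("matrix correlation is exact on known cases", {
  mk <- function(counts) {
    dimnames(counts) <- list(source = 1:nrow(counts), receiver = 1:ncol(counts))
    structure(list(percent = counts, counts = counts,
                   released = rep(10, nrow(counts)), meta = list()),
              class = "connectivity_matrix")
  }
  m1 <- mk(matrix(c(5, 1, 0, 3), 2))
  expect_identical(matrix_correlation(m1, m1), 1)
  m2 <- mk(2 * m1$counts)
  expect_equal(matrix_correlation(m1, m2), 1)

  a <- mk(matrix(c(1, 2, 3, 0), 2))
  b <- mk(matrix(c(3, 2, 1, 0), 2))
  # anti-ordered counts {1,2,3} vs {3,2,1} with a shared zero
  expect_equal(stats::cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(matrix_correlation(a, b),
               stats::cor(as.vector(a$counts), as.vector(b$counts)))

  z <- mk(matrix(0, 2, 2))
  expect_warning(r <- matrix_correlation(z, m1),
                 class = "capdrift_warning_degenerate")
  expect_true(is.na(r))

  m3 <- mk(matrix(1:9, 3))
  expect_error(matrix_correlation(m1, m3), class = "capdrift_error_validation")
})

test_that("per-step visit logging agrees with post-hoc detection at full resolution", {
  params <- fix_params()
  b <- fix_bathy()
  flow <- fix_flow_steady()
  sponge <- areas_in_group(fix_areas(), "sponge")
  seeds <- seed_areas(sponge[sponge$area_id %in% c(5, 6), ], 0.06, 1245, b)
  cfg <- tracker_config(K_h = 100, duration_days = 4, seed = 17,
                        record_every = 1, domain_box = cap_domain_box())
  tr <- track_particles(seeds, flow, cfg, bathy = b, areas = sponge)
  vt_inline <- detect_visits(tr, sponge)
  tr2 <- tr
  tr2$visits <- NULL
  vt_post <- detect_visits(tr2, sponge)
  expect_equal(as.data.frame(vt_inline$visits), as.data.frame(vt_post$visits))
  expect_equal(vt_inline$particles, vt_post$particles)
})
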