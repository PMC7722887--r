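# Gridded field model, plain-text I/O, and space-time interpolation.

test_that("field files round-trip bit-exactly and validate their structure", {
  fl <- small_flow(u = 0.1, v = -0.05, w = 1e-5, nt = 12)
  fl$u[2, 2, 2, ] <- 0.123456789012345     # non-trivial digits
  fl <- flow_field(fl$grid, fl$u, fl$v, fl$w, months = 1:12, wet = fl$wet)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field(fl, path)
  back <- read_field(path, kind = "flow")
  expect_identical(back$u, fl$u)
  expect_identical(back$v, fl$v)
  expect_identical(back$w, fl$w)
  expect_identical(back$grid$lons, fl$grid$lons)

  # masked cells survive as sentinels
  wet <- fl$wet; wet[1, 1, ] <- FALSE
  fl2 <- flow_field(fl$grid, fl$u, fl$v, fl$w, months = 1:12, wet = wet)
  write_field(fl2, path)
  back2 <- read_field(path)
  expect_true(all(is.na(back2$u[1, 1, , ])))
  expect_false(any(back2$wet[1, 1, ]))

  # bathymetry round trip, including land as NA
  b <- fix_bathy()
  bp <- withr::local_tempfile(fileext = ".tsv")
  write_field(b, bp)
  b2 <- read_field(bp, kind = "bathymetry")
  expect_identical(b2$seafloor_depth, b$seafloor_depth)

  expect_error(write_field(fl, ""), class = "capdrift_error_io")
  expect_error(read_field(path, kind = "scalar"), class = "capdrift_error_format")
})

test_that("descending latitude axes are normalized on read", {
  fl <- small_flow(u = 0, nt = 1)
  # u increases with latitude so reordering is observable
  for (j in seq_along(fl$grid$lats)) fl$u[, j, , ] <- j / 100
  fl <- flow_field(fl$grid, fl$u, fl$v, fl$w, months = NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field(fl, path)

  # flip the lat axis in the stored header and remap the lat indices
  lines <- readLines(path)
  ny <- length(fl$grid$lats)
  ih <- grep("^# lats:", lines)
  lats_rev <- rev(fl$grid$lats)
  lines[ih] <- paste0("# lats: ", paste(sprintf("%.17g", lats_rev), collapse = ","))
  hdr_n <- grep("^ix\t", lines)
  body <- read.table(text = lines[(hdr_n + 1):length(lines)], sep = "\t")
  names(body) <- strsplit(lines[hdr_n], "\t")[[1]]
  body$iy <- ny + 1L - body$iy
  lines <- c(lines[1:hdr_n],
             do.call(paste, c(unname(as.list(body)), sep = "\t")))
  writeLines(lines, path)

  back <- read_field(path, kind = "flow")
  expect_true(all(diff(back$grid$lats) > 0))
  # point samples agree with the original field after reordering
  s0 <- sample_velocity(fl, -45.1, 47.3, 200, 0)
  s1 <- sample_velocity(back, -45.1, 47.3, 200, 0)
  expect_equal(s1$u, s0$u)
})

test_that("flow files without a depth axis are rejected with a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# capdrift field v1", "# kind: flow",
    "# lons: -46,-45", "# lats: 46,47", "# months: NA",
    "ix\tiy\tiz\tit\tu\tv\tw", "1\t1\t1\t1\t0\t0\t0"
  ), path)
  expect_error(read_field(path, kind = "flow"), "depth",
               class = "capdrift_error_format")
})

test_that("constructors enforce axis and shape invariants", {
  expect_error(ocean_grid(c(-45, -46), 46:47, c(0, 10)),
               class = "capdrift_error_validation")
  expect_error(ocean_grid(-46:-45, 46:47, 5), class = "capdrift_error_validation")
  g <- ocean_grid(c(-46, -45), c(46, 47), c(0, 100))
  expect_error(flow_field(g, array(0, c(2, 2, 2, 1)), array(0, c(2, 2, 2, 1)),
                          array(0, c(2, 2, 1, 1)), months = NA),
               class = "capdrift_error_validation")
  expect_error(flow_field(g, array(9, c(2, 2, 2, 1)), array(0, c(2, 2, 2, 1)),
                          array(0, c(2, 2, 2, 1)), months = NA),
               class = "capdrift_error_validation")  # |u| sanity bound
  expect_error(bathymetry(c(-46, -45), c(46, 47), matrix(-5, 2, 2)),
               class = "capdrift_error_validation")
})

test_that("velocity interpolation is exact on constants, nodes and linear ramps", {
  # constant field anywhere
  fl <- small_flow(u = 0.1)
  s <- sample_velocity(fl, c(-45.31, -44.2), c(46.7, 47.9), c(40, 900), 0)
  expect_equal(s$u, c(0.1, 0.1))
  expect_equal(s$v, c(0, 0))
  expect_equal(s$w, c(0, 0))

  # node values reproduced exactly on a random field
  set.seed(5)
  grid <- ocean_grid(seq(-46, -45, 0.25), seq(46, 47, 0.25), c(0, 50, 300))
  dm <- c(5, 5, 3, 1)
  fl2 <- flow_field(grid, array(runif(prod(dm), -1, 1), dm),
                    array(runif(prod(dm), -1, 1), dm),
                    array(runif(prod(dm), -0.05, 0.05), dm), months = NA)
  nodes <- expand.grid(i = 1:5, j = 1:5, k = 1:3)
  s2 <- sample_velocity(fl2, grid$lons[nodes$i], grid$lats[nodes$j],
                        grid$depths[nodes$k], 0)
  expect_equal(s2$u, fl2$u[cbind(nodes$i, nodes$j, nodes$k, 1)])

  # midway between nodes differing only in u (0 vs 0.2) -> 0.1
  fl3 <- small_flow(u = 0)
  fl3$u[, , , ] <- 0
  i <- 2; j <- 2
  fl3$u[i, j, 1, 1] <- 0; fl3$u[i + 1, j, 1, 1] <- 0.2
  fl3 <- flow_field(fl3$grid, fl3$u, fl3$v, fl3$w, months = NA)
  mid <- (fl3$grid$lons[i] + fl3$grid$lons[i + 1]) / 2
  s3 <- sample_velocity(fl3, mid, fl3$grid$lats[j], 0, 0)
  expect_equal(s3$u, 0.1)

  # exact on fields linear in each coordinate (trilinear reproduces them)
  set.seed(6)
  coef <- runif(4, -1, 1)
  lin <- function(lon, lat, depth) {
    coef[1] + coef[2] * (lon + 45) + coef[3] * (lat - 46) + coef[4] * depth / 1000
  }
  u <- array(0, dm)
  for (i in 1:5) for (j in 1:5) for (k in 1:3) {
    u[i, j, k, 1] <- lin(grid$lons[i], grid$lats[j], grid$depths[k])
  }
  fl4 <- flow_field(grid, u, array(0, dm), array(0, dm), months = NA)
  pts <- data.frame(lon = runif(20, -46, -45), lat = runif(20, 46, 47),
                    depth = runif(20, 0, 300))
  s4 <- sample_velocity(fl4, pts$lon, pts$lat, pts$depth, 0)
  expect_equal(s4$u, lin(pts$lon, pts$lat, pts$depth), tolerance = 1e-12)
})

test_that("temporal interpolation wraps December to January", {
  fl <- small_flow(u = 0, nt = 12)
  for (m in 1:12) fl$u[, , , m] <- m / 100
  fl <- flow_field(fl$grid, fl$u, fl$v, fl$w, months = 1:12)
  # 11.9 sits between the December (11.5) and January (0.5) month centres
  s <- sample_velocity(fl, -45, 47, 10, 11.9)
  expect_equal(s$u, 0.6 * 12 / 100 + 0.4 * 1 / 100)
  # month centres return the stored slice
  s2 <- sample_velocity(fl, -45, 47, 10, 2.5)
  expect_equal(s2$u, 3 / 100)
})

test_that("masked neighbours are renormalized, fully-masked is grounded, outside is out-of-domain", {
  fl <- small_flow(u = 0.4)
  wet <- fl$wet
  wet[, , 3:4] <- FALSE          # only top two levels wet
  wet[1:2, , ] <- FALSE          # westernmost columns fully masked
  fl <- flow_field(fl$grid, fl$u, fl$v, fl$w, months = NA, wet = wet)

  # renormalization: point adjacent to masked cells still returns 0.4
  s <- sample_velocity(fl, -44.4, 46.8, 290, 0)
  expect_equal(s$u, 0.4)
  expect_equal(s$status, "ok")

  s2 <- sample_velocity(fl, -45.9, 47, 50, 0)   # all-masked neighbourhood
  expect_equal(s2$status, "grounded")
  expect_true(is.na(s2$u))

  s3 <- sample_velocity(fl, -40, 47, 50, 0)     # outside the grid box
  expect_equal(s3$status, "out_of_domain")
})

test_that("scalar sampling and bottom values follow the same kernel", {
  grid <- ocean_grid(c(-46, -45), c(46, 47), c(10, 100, 500))
  dm <- c(2, 2, 3, 12)
  vals <- array(rep(c(5, 4, 3), each = 4), dm)  # 5, 4, 3 degC by level
  tf <- scalar_field(grid, vals, "temperature")
  expect_equal(sample_scalar(tf, -45.5, 46.5, 55, 0)$value, 4.5)

  # column [5, 4, 3] -> bottom 3 degC at the deepest level
  bv <- bottom_value(tf, -45.99, 46.01, 0)
  expect_equal(bv$value, 3)
  expect_equal(bv$bottom_depth, 500)

  # deepest level masked -> next-deepest value
  wet <- array(TRUE, c(2, 2, 3)); wet[1, 1, 3] <- FALSE
  tf2 <- scalar_field(grid, vals, "temperature", wet = wet)
  expect_equal(bottom_value(tf2, -46, 46, 0)$value, 4)

  # land column -> grounded
  wet[1, 1, ] <- FALSE
  tf3 <- scalar_field(grid, vals, "temperature", wet = wet)
  expect_equal(bottom_value(tf3, -46, 46, 0)$status, "grounded")
  expect_equal(sample_scalar(tf3, -46, 46, 50, 0)$status, "grounded")

  # midpoint between 2 and 4 degC -> 3 degC
  v2 <- array(2, dm); v2[2, , , ] <- 4
  tf4 <- scalar_field(grid, v2, "temperature")
  expect_equal(sample_scalar(tf4, -45.5, 46.2, 20, 3)$value, 3)
})
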