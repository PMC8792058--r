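test_that("nearest-neighbour resampling honours cell geometry", {
  const <- rg(matrix(5, 8, 8), cell = 10)
  up <- resample_nearest(const, 5)
  expect_true(all(up$values == 5))
  expect_equal(dim(up$values), c(16L, 16L))

  r22 <- rg(matrix(c(1, 3, 2, 4), 2, 2), cell = 10)
  up2 <- resample_nearest(r22, 5)
  expect_equal(up2$values,
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))

  # down-then-up at the same factor only ever reuses original values
  set.seed(3)
  smooth <- rg(smooth_field_fixture(12), cell = 10)
  rt <- resample_nearest(resample_nearest(smooth, 20), 10)
  expect_true(all(rt$values %in% smooth$values))

  expect_error(resample_nearest(const, 15), "multiple or divisor")
})

test_that("Horn slope and aspect match analytic planes", {
  n <- 9; cell <- 10
  xs <- matrix(rep((1:n - 0.5) * cell, each = n), n, n)
  ys <- matrix(rep(rev(1:n - 0.5) * cell, times = n), n, n)

  flat <- slope_aspect(rg(matrix(7, n, n), cell = cell))
  expect_true(all(flat$slope$values[2:8, 2:8] == 0))
  expect_true(all(flat$aspect$values[2:8, 2:8] == 0))
  expect_true(all(is.na(flat$slope$values[1, ])))   # border nodata

  # z = -0.5 x: falls eastward, so the slope faces east (pi/2)
  east <- slope_aspect(rg(-0.5 * xs, cell = cell))
  expect_equal(unique(as.vector(round(east$slope$values[2:8, 2:8], 10))),
               round(atan(0.5), 10))
  expect_equal(unique(as.vector(round(east$aspect$values[2:8, 2:8], 10))),
               round(pi / 2, 10))

  # z = -1.0 y: falls northward -> aspect 0 (north-facing downslope)
  north <- slope_aspect(rg(-1.0 * ys, cell = cell))
  expect_equal(unique(as.vector(round(north$slope$values[2:8, 2:8], 10))),
               round(atan(1), 10))
  expect_equal(unique(as.vector(round(north$aspect$values[2:8, 2:8], 10))), 0)

  expect_error(slope_aspect(rg(matrix(0, 2, 5))), "3 x 3")
})

test_that("northness and eastness are the aspect cosine and sine", {
  asp <- rg(matrix(c(0, pi / 2, pi, 3 * pi / 2, NA, 1), 2, 3))
  ne <- northness_eastness(asp)
  expect_equal(ne$northness$values[1:4], c(1, 0, -1, 0), tolerance = 1e-12)
  expect_equal(ne$eastness$values[1:4], c(0, 1, 0, -1), tolerance = 1e-12)
  expect_true(is.na(ne$northness$values[1, 3]))
  expect_true(all(ne$northness$values^2 + ne$eastness$values^2 <= 1 + 1e-9,
                  na.rm = TRUE))
})

test_that("TRI matches hand arithmetic and the brute-force oracle", {
  expect_true(all(tri(rg(matrix(4, 5, 5)))$values == 0))

  m <- matrix(1, 3, 3); m[2, 2] <- 2
  expect_equal(tri(rg(m))$values[2, 2], 1)

  # borders use the available 3 or 5 neighbours
  expect_equal(tri(rg(m))$values[1, 1], mean(c(0, 1, 0)))

  set.seed(7)
  for (i in 1:25) {
    mm <- matrix(rnorm(25), 5, 5)
    expect_equal(tri(rg(mm))$values, tri_oracle(mm))
  }
})

test_that("TCI is the within-block 3D/2D surface ratio", {
  flat <- rg(matrix(1234, 20, 20), cell = 10)
  expect_equal(tci(flat, 50)$values, matrix(1, 4, 4))

  n <- 20; cell <- 10
  xs <- matrix(rep((1:n - 0.5) * cell, each = n), n, n)
  plane45 <- rg(xs, cell = cell)   # dz/dx = 1 everywhere
  v <- tci(plane45, 50)$values
  expect_equal(unique(round(as.vector(v), 6)), round(sqrt(2), 6),
               tolerance = 1e-6)

  set.seed(8)
  bumpy <- rg(smooth_field_fixture(30) * 40, cell = 10)
  expect_true(all(tci(bumpy, 50)$values >= 1))
})

test_that("heterogeneity indices respond correctly to DEM transforms", {
  set.seed(9)
  m <- smooth_field_fixture(24) * 30
  dem <- rg(m, cell = 10)
  # both indices ignore a constant elevation shift
  expect_equal(tri(dem)$values, tri(rg(m + 500, cell = 10))$values)
  expect_equal(tci(dem, 40)$values, tci(rg(m + 500, cell = 10), 40)$values)
  # TRI is linear in vertical exaggeration, TCI is not
  expect_equal(tri(rg(2 * m, cell = 10))$values, 2 * tri(dem)$values)
  expect_false(isTRUE(all.equal(tci(rg(2 * m, cell = 10), 40)$values,
                                2 * tci(dem, 40)$values)))
})

test_that("the irradiation proxy favours south-facing slopes", {
  slope <- rg(matrix(0.4, 3, 3))
  asp_s <- rg(matrix(pi, 3, 3))
  asp_n <- rg(matrix(0, 3, 3))
  south <- dni_proxy(slope, asp_s, latitude_deg = 46)
  north <- dni_proxy(slope, asp_n, latitude_deg = 46)
  expect_true(all(south$values > north$values))
  flat <- dni_proxy(rg(matrix(0, 3, 3)), rg(matrix(0, 3, 3)), 46)
  expect_length(unique(as.vector(flat$values)), 1L)
  expect_true(all(south$values > 0) && all(north$values > 0))
})
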