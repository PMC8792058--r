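test_that("landscape configuration enforces its invariants", {
  expect_error(landscape_config(extent_cells = c(30, 30), coarse_factor = 20),
               "divisible")
  expect_error(landscape_config(plateau_elevation_m = 1000,
                                valley_elevation_m = 2000), "exceed")
  expect_error(landscape_config(carbonate_fraction = 0), "\\(0, 1]")
  expect_error(landscape_config(rcp_offsets_K = c(2.5)), "named")
})

test_that("DEM respects the elevation range and is seed-deterministic", {
  cfg <- landscape_config(extent_cells = c(60, 60), coarse_factor = 20,
                          plateau_elevation_m = 3000,
                          valley_elevation_m = 1000, seed = 5)
  dem <- make_dem(cfg)
  expect_lte(max(dem$values), 3000)
  expect_gte(min(dem$values), 1000)
  expect_identical(dem$values, make_dem(cfg)$values)
  dem2 <- make_dem(landscape_config(extent_cells = c(60, 60),
                                    coarse_factor = 20,
                                    plateau_elevation_m = 3000,
                                    valley_elevation_m = 1000, seed = 6))
  expect_false(identical(dem$values, dem2$values))
})

test_that("DEM hypsometry is steepest in the middle elevation band", {
  # flat valley floors, steep mid-slopes, flat highlands: the median slope
  # of the middle equal-width elevation band exceeds both others
  for (seed in c(1, 7)) {
    dem <- make_dem(landscape_config(seed = seed))
    slope <- slope_aspect(dem)$slope
    e <- as.vector(dem$values)
    s <- as.vector(slope$values)
    band <- cut(e, seq(min(e), max(e), length.out = 4), include.lowest = TRUE)
    med <- tapply(s, band, median, na.rm = TRUE)
    expect_gt(med[2], med[1])
    expect_gt(med[2], med[3])
  }
})

test_that("bioclim scenarios have 19 layers and the configured structure", {
  cfg <- landscape_config(extent_cells = c(100, 100), seed = 2)
  demc <- block_aggregate(make_dem(cfg), cfg$coarse_factor)
  scen <- make_bioclim(demc, cfg)
  expect_length(scen, 1 + cfg$n_gcms * length(cfg$rcp_offsets_K))
  expect_true(all(vapply(scen, function(s) length(s$layers) == 19L, TRUE)))

  # temperature lapse is recovered by regression on coarse elevation
  fit <- lm(as.vector(scen$baseline$layers$bio01$values) ~
              I(as.vector(demc$values) / 1000))
  expect_equal(-unname(coef(fit)[2]), cfg$lapse_rate_K_per_km, tolerance = 0.05)
})

test_that("zero warming and zero jitter reproduce the baseline exactly", {
  cfg <- landscape_config(extent_cells = c(60, 60), coarse_factor = 20,
                          rcp_offsets_K = c(rcp45 = 0), gcm_jitter_sd = 0,
                          n_gcms = 2, seed = 3)
  demc <- block_aggregate(make_dem(cfg), cfg$coarse_factor)
  scen <- make_bioclim(demc, cfg)
  for (nm in names(scen$baseline$layers))
    expect_identical(scen$GCM1_rcp45$layers[[nm]]$values,
                     scen$baseline$layers[[nm]]$values)
})

test_that("warming offsets shift temperature-like layers by the offset", {
  cfg <- landscape_config(extent_cells = c(60, 60), coarse_factor = 20,
                          rcp_offsets_K = c(rcp45 = 2.5), gcm_jitter_sd = 0,
                          n_gcms = 1, seed = 3)
  demc <- block_aggregate(make_dem(cfg), cfg$coarse_factor)
  scen <- make_bioclim(demc, cfg)
  expect_equal(scen$GCM1_rcp45$layers$bio01$values,
               scen$baseline$layers$bio01$values + 2.5)
  # precipitation-like layers do not warm
  expect_equal(scen$GCM1_rcp45$layers$bio12$values,
               scen$baseline$layers$bio12$values)
})

test_that("geology mask hits the requested carbonate fraction", {
  dem <- make_dem(landscape_config(extent_cells = c(100, 100), seed = 4))
  expect_true(all(make_geology_mask(dem, 1, seed = 1)$values == 1))
  g <- make_geology_mask(dem, 0.6, seed = 1)
  expect_true(all(g$values %in% c(0, 1)))
  frac <- mean(g$values)
  expect_gte(frac, 0.55)
  expect_lte(frac, 0.65)
  expect_identical(g$values, make_geology_mask(dem, 0.6, seed = 1)$values)
  expect_false(identical(g$values, make_geology_mask(dem, 0.6, seed = 2)$values))
  expect_error(make_geology_mask(dem, 1.2, seed = 1), "\\(0, 1]")
})

test_that("virtual species sampling respects suitability and geology", {
  d <- 40
  pc1 <- rg(matrix(rnorm(d^2), d), cell = 50)
  pc2 <- rg(matrix(rnorm(d^2), d), cell = 50)
  geol <- rg(matrix(1, d, d), cell = 50)
  truth <- species_truth("sp", c(0, 0), c(1, 1), n_occurrences = 100)

  occ <- make_species(truth, pc1, pc2, geol, seed = 9)
  suit <- true_suitability(truth, pc1, pc2, geol)
  s_at <- extract_values(suit, occ$x, occ$y)
  expect_true(all(s_at > 0))
  # sampled cells are climatically better than the landscape average
  expect_gt(mean(s_at), mean(suit$values))

  # geology restricted to one cell pins every occurrence to that cell
  g1 <- rg(matrix(0, d, d), cell = 50)
  g1$values[17, 23] <- 1
  occ1 <- make_species(truth, pc1, pc2, g1, seed = 9)
  idx <- cell_of(g1, occ1$x, occ1$y)
  expect_true(all(idx$row == 17 & idx$col == 23))

  g0 <- rg(matrix(0, d, d), cell = 50)
  expect_error(make_species(truth, pc1, pc2, g0, seed = 9), "empty niche")
})

test_that("species truth validates its invariants", {
  expect_error(species_truth("a", c(0, 0), c(1, 1), n_occurrences = 30),
               "exceed 30")
  expect_error(species_truth("a", c(0, 0), c(1, 0), n_occurrences = 50),
               "positive")
})

test_that("thinning keeps the first occurrence per cell", {
  grid <- rg(matrix(0, 10, 10), cell = 50)
  pts <- data.frame(x = rep(12, 10), y = rep(487, 10), id = 1:10)
  thin <- thin_occurrences(pts, grid)
  expect_equal(nrow(thin), 1L)
  expect_equal(thin$id, 1L)   # first in input order wins

  pts7 <- data.frame(x = (0:6) * 50 + 25, y = rep(25, 7))
  expect_equal(nrow(thin_occurrences(pts7, grid)), 7L)

  expect_equal(nrow(thin_occurrences(pts7[0, ], grid)), 0L)

  # random points: retained count equals occupied-cell count by a hash oracle
  set.seed(42)
  ptsr <- data.frame(x = runif(200, 0, 500), y = runif(200, 0, 500))
  idx <- cell_of(grid, ptsr$x, ptsr$y)
  expect_equal(nrow(thin_occurrences(ptsr, grid)),
               length(unique(paste(idx$row, idx$col))))
})
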