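#' Configure a synthetic mountain landscape
#'
#' Describes the virtual study area every pipeline stage is exercised on:
#' a fine analysis grid (50 m by default) with a coarse climate grid on top
#' of it (`coarse_factor` fine cells per coarse cell side, default 20,
#' emulating ~1 km climate rasters over a 50 m analysis grid), plateau
#' topography, an elevational temperature lapse, per-rcp warming offsets
#' and per-GCM perturbations.
#'
#' @param extent_cells integer pair: rows, cols of the fine grid; both must
#'   be divisible by `coarse_factor`.
#' @param fine_cell_m fine cell size in metres.
#' @param coarse_factor fine cells per coarse cell side.
#' @param plateau_elevation_m,valley_elevation_m elevation range in metres
#'   (plateau must exceed valley).
#' @param lapse_rate_K_per_km temperature lapse rate applied to the
#'   temperature-like bioclimatic layers.
#' @param rcp_offsets_K named numeric vector: mean warming per rcp scenario
#'   (defaults +2.5 K for rcp 4.5 and +4.5 K for rcp 8.5, 2061-2080 horizon).
#' @param gcm_jitter_sd standard deviation (K) of the smooth per-GCM
#'   perturbation fields.
#' @param n_gcms number of general circulation models emulated.
#' @param n_plateaus number of high plateaus in the DEM.
#' @param carbonate_fraction fraction of the landscape on carbonate bedrock.
#' @param seed integer master seed; every generated artefact is a pure
#'   function of the configuration and this seed.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(extent_cells = c(200L, 200L),
                             fine_cell_m = 50,
                             coarse_factor = 20L,
                             plateau_elevation_m = 2800,
                             valley_elevation_m = 1200,
                             lapse_rate_K_per_km = 6.5,
                             rcp_offsets_K = c(rcp45 = 2.5, rcp85 = 4.5),
                             gcm_jitter_sd = 0.15,
                             n_gcms = 5L,
                             n_plateaus = 2L,
                             carbonate_fraction = 0.7,
                             seed = 1L) {
  extent_cells <- as.integer(extent_cells)
  if (length(extent_cells) != 2L || any(extent_cells <= 0L))
    stop("`extent_cells` must be two positive integers")
  coarse_factor <- as.integer(coarse_factor)
  if (any(extent_cells %% coarse_factor != 0L))
    stop("`extent_cells` must be divisible by `coarse_factor`")
  if (plateau_elevation_m <= valley_elevation_m)
    stop("`plateau_elevation_m` must exceed `valley_elevation_m`")
  if (is.null(names(rcp_offsets_K)) || any(!nzchar(names(rcp_offsets_K))))
    stop("`rcp_offsets_K` must be a named vector (one offset per rcp)")
  if (carbonate_fraction <= 0 || carbonate_fraction > 1)
    stop("`carbonate_fraction` must be in (0, 1]")
  structure(
    list(extent_cells = extent_cells, fine_cell_m = fine_cell_m,
         coarse_factor = coarse_factor,
         plateau_elevation_m = plateau_elevation_m,
         valley_elevation_m = valley_elevation_m,
         lapse_rate_K_per_km = lapse_rate_K_per_km,
         rcp_offsets_K = rcp_offsets_K, gcm_jitter_sd = gcm_jitter_sd,
         n_gcms = as.integer(n_gcms), n_plateaus = as.integer(n_plateaus),
         carbonate_fraction = carbonate_fraction, seed = as.integer(seed)),
    class = "landscape_config"
  )
}

#' Generate the synthetic digital elevation model
#'
#' Builds a DEM with the hypsometry typical of dolomitic massifs: flat
#' valley floors, steep mid-elevation slopes, and flat summit plateaus.
#' The surface is a sum of smoothed plateau masks (logistic shoulders
#' around seeded plateau centres), a gentle regional tilt and low-amplitude
#' smoothed noise, clamped to the configured elevation range.  Plateau
#' centres are drawn in relative coordinates, so the same seed yields the
#' same macro-topography at any grid resolution.
#'
#' @param config a [landscape_config].
#' @return a [raster_grid] DEM in metres a.s.l.
#' @export
make_dem <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$extent_cells[1]
  nc <- config$extent_cells[2]
  cell <- config$fine_cell_m
  relief <- config$plateau_elevation_m - config$valley_elevation_m
  width_m <- nc * cell
  height_m <- nr * cell

  # massif centres: evenly spread anchors with a little seeded jitter, in
  # relative coordinates so the layout is resolution independent
  k <- config$n_plateaus
  anchors <- cbind(seq(0.3, 0.7, length.out = k),
                   seq(0.35, 0.65, length.out = k))
  centres <- with_seed(fan_seed(config$seed, "dem-centres"), {
    anchors + matrix(runif(2 * k, -0.08, 0.08), k, 2)
  })
  # each massif carries a few summit cones scattered over its highland
  n_summits <- 3L
  summits <- with_seed(fan_seed(config$seed, "dem-summits"), {
    do.call(rbind, lapply(seq_len(k), function(i) {
      ang <- runif(n_summits, 0, 2 * pi)
      rad <- sqrt(runif(n_summits)) * 0.45
      cbind(centres[i, 1] + rad * cos(ang) * 3000 / width_m,
            centres[i, 2] + rad * sin(ang) * 3000 / height_m)
    }))
  })

  # metric cell-centre coordinates (column-major over rows)
  x <- (rep(seq_len(nc), each = nr) - 0.5) * cell
  y <- (rep(seq_len(nr), times = nc) - 0.5) * cell
  # geomorphic scales in metres: a ~3 km highland radius with ~450 m wide
  # logistic shoulders and ~600 m summit cones
  r0 <- 3000
  w <- 450
  sigma_peak <- 600
  dmin <- rep(Inf, nr * nc)
  for (i in seq_len(k)) {
    dk <- sqrt((x - centres[i, 1] * width_m)^2 + (y - centres[i, 2] * height_m)^2)
    dmin <- pmin(dmin, dk)
  }
  shoulder <- 1 / (1 + exp(-(r0 - dmin) / w))
  peakfield <- rep(0, nr * nc)
  for (i in seq_len(nrow(summits))) {
    ds <- sqrt((x - summits[i, 1] * width_m)^2 + (y - summits[i, 2] * height_m)^2)
    peakfield <- pmax(peakfield, exp(-(ds / sigma_peak)^2))
  }
  tilt <- 0.05 * (x / width_m + y / height_m) / 2
  noise <- with_seed(fan_seed(config$seed, "dem-noise"), {
    smooth_gaussian(matrix(rnorm(nr * nc), nr, nc), sigma = 3) * 6
  })
  z <- matrix(config$valley_elevation_m +
                relief * (0.72 * shoulder + 0.28 * peakfield + tilt),
              nr, nc) + noise
  z <- pmin(pmax(z, config$valley_elevation_m), config$plateau_elevation_m)
  raster_grid(z, xmin = 0, ymax = nr * cell, cell = cell)
}

# Layer roles mirror the usual bioclimatic set: bio01-bio07 temperature-like,
# bio08-bio11 temperature/precipitation mixtures, bio12-bio19 precipitation-like.
bioclim_layer_names <- function() sprintf("bio%02d", 1:19)

#' @rdname make_bioclim
#' @export
temperature_like_layers <- function() sprintf("bio%02d", 1:11)

#' Generate baseline and future bioclimatic scenarios
#'
#' Produces 19 mutually correlated bioclimatic layers on the coarse climate
#' grid, driven by elevation: seven temperature-like layers decreasing with
#' elevation at the configured lapse rate, eight precipitation-like layers
#' increasing orographically, and four temperature/precipitation mixtures,
#' each with smooth correlated noise.  Future scenarios add the configured
#' rcp warming offset (weighted by each layer's temperature content) plus a
#' smooth per-GCM perturbation field.
#'
#' @param dem_coarse the DEM block-averaged to the coarse grid.
#' @param config a [landscape_config].
#' @return A named list of `climate_scenario` objects: `baseline` plus one
#'   per (GCM, rcp) combination, named e.g. `"GCM2_rcp45"`.  Each scenario
#'   holds `tag`, `rcp`, `gcm` and `layers` (named list of 19 rasters).
#' @export
make_bioclim <- function(dem_coarse, config) {
  stopifnot(inherits(dem_coarse, "raster_grid"), inherits(config, "landscape_config"))
  if (length(config$rcp_offsets_K) == 0L) stop("no rcp offsets configured")
  elev_km <- dem_coarse$values / 1000
  d <- dim(elev_km)
  lapse <- config$lapse_rate_K_per_km

  layer_field <- function(base, slope_per_km, noise_sd, key) {
    noise <- with_seed(fan_seed(config$seed, "bioclim", key), {
      smooth_gaussian(matrix(rnorm(prod(d)), d[1], d[2]), sigma = 2) * noise_sd
    })
    base + slope_per_km * elev_km + noise
  }

  nm <- bioclim_layer_names()
  temp_weight <- setNames(numeric(19), nm)
  layers <- vector("list", 19)
  names(layers) <- nm
  # temperature-like: annual/seasonal means and extremes (deg C)
  temp_base <- c(14, 22, 40, 650, 24, -4, 28)
  for (k in 1:7) {
    layers[[k]] <- layer_field(temp_base[k], -lapse, 0.35, nm[k])
    temp_weight[k] <- 1
  }
  # mixtures: temperature of wet/dry/warm/cold quarters (deg C, partly
  # precipitation-coupled)
  mix_temp <- c(0.8, 0.7, 0.9, 0.6)
  for (k in 8:11) {
    base <- c(9, 15, 12, -1)[k - 7]
    layers[[k]] <- layer_field(base, -lapse * mix_temp[k - 7], 0.45, nm[k])
    temp_weight[k] <- mix_temp[k - 7]
  }
  # precipitation-like: orographic increase with elevation plus an
  # elevation-independent moisture-advection gradient (windward/leeward),
  # shared across the precipitation layers so a second climate axis with
  # real spatial variance exists
  moisture <- {
    xg <- matrix(rep((seq_len(d[2]) - 0.5) / d[2] - 0.5, each = d[1]), d[1], d[2])
    noise <- with_seed(fan_seed(config$seed, "moisture"), {
      smooth_gaussian(matrix(rnorm(prod(d)), d[1], d[2]), sigma = 2)
    })
    2 * xg + 0.6 * noise
  }
  prec_base <- c(900, 140, 35, 60, 320, 180, 300, 260)
  prec_slope <- c(350, 60, 12, 25, 120, 70, 110, 95)
  for (k in 12:19) {
    layers[[k]] <- pmax(
      layer_field(prec_base[k - 11], prec_slope[k - 11], 18, nm[k]) +
        4.0 * prec_slope[k - 11] * moisture, 0)
    temp_weight[k] <- 0
  }

  as_rasters <- function(lst) lapply(lst, function(m)
    raster_grid(m, xmin = dem_coarse$xmin, ymax = dem_coarse$ymax,
                cell = dem_coarse$cell))

  scenarios <- list(baseline = structure(
    list(tag = "baseline", rcp = NA_character_, gcm = NA_character_,
         layers = as_rasters(layers)),
    class = "climate_scenario"))

  gcms <- sprintf("GCM%d", seq_len(config$n_gcms))
  for (rcp in names(config$rcp_offsets_K)) {
    offset <- config$rcp_offsets_K[[rcp]]
    for (g in gcms) {
      fut <- layers
      for (k in 1:19) {
        jitter <- if (config$gcm_jitter_sd > 0) {
          with_seed(fan_seed(config$seed, "gcm-jitter", g, rcp, nm[k]), {
            smooth_gaussian(matrix(rnorm(prod(d)), d[1], d[2]), sigma = 2) *
              config$gcm_jitter_sd
          })
        } else 0
        fut[[k]] <- fut[[k]] + offset * temp_weight[k] + jitter
      }
      tag <- paste(g, rcp, sep = "_")
      scenarios[[tag]] <- structure(
        list(tag = tag, rcp = rcp, gcm = g, layers = as_rasters(fut)),
        class = "climate_scenario")
    }
  }
  scenarios
}

#' Generate a binary carbonate-geology mask
#'
#' Spatially autocorrelated bedrock patches: a smoothed Gaussian random
#' field thresholded at the quantile matching the requested carbonate
#' fraction, so the realised fraction of 1-cells matches it (up to ties).
#'
#' @param dem a [raster_grid] providing the target grid.
#' @param carbonate_fraction fraction of cells on carbonate, in (0, 1].
#' @param seed integer seed.
#' @return a binary [raster_grid] (1 = carbonate).
#' @export
make_geology_mask <- function(dem, carbonate_fraction, seed) {
  if (!is.numeric(carbonate_fraction) || carbonate_fraction <= 0 ||
      carbonate_fraction > 1)
    stop("`carbonate_fraction` must be in (0, 1]")
  d <- dim(dem$values)
  if (carbonate_fraction == 1)
    return(raster_grid(matrix(1, d[1], d[2]), xmin = dem$xmin,
                       ymax = dem$ymax, cell = dem$cell))
  field <- with_seed(fan_seed(seed, "geology"), {
    smooth_gaussian(matrix(rnorm(prod(d)), d[1], d[2]), sigma = 4)
  })
  thr <- quantile(field, 1 - carbonate_fraction, names = FALSE)
  raster_grid(matrix(as.numeric(field >= thr), d[1], d[2]),
              xmin = dem$xmin, ymax = dem$ymax, cell = dem$cell)
}

#' Define a virtual species with a known climatic niche
#'
#' @param species_id character id.
#' @param niche_center length-2 vector: niche optimum on the (PC1, PC2)
#'   climate axes.
#' @param niche_breadth length-2 positive vector: Gaussian niche standard
#'   deviations along the two axes.
#' @param n_occurrences number of occurrences to sample (> 30, the
#'   modelling floor).
#' @param prevalence fraction of the landscape counted as truly suitable
#'   when the ground-truth range is binarised (see [true_suitable_area()]).
#' @return An object of class `species_truth`.
#' @export
species_truth <- function(species_id, niche_center, niche_breadth,
                          n_occurrences, prevalence = 0.1) {
  if (n_occurrences <= 30) stop("`n_occurrences` must exceed 30")
  if (any(niche_breadth <= 0)) stop("`niche_breadth` must be strictly positive")
  structure(
    list(species_id = as.character(species_id),
         niche_center = as.numeric(niche_center),
         niche_breadth = as.numeric(niche_breadth),
         n_occurrences = as.integer(n_occurrences),
         prevalence = prevalence),
    class = "species_truth"
  )
}

#' True suitability surface of a virtual species
#'
#' Gaussian kernel around the niche centre in (PC1, PC2) space, restricted
#' to carbonate bedrock.
#'
#' @param truth a [species_truth].
#' @param pc1,pc2 fine-grid climate-axis rasters.
#' @param geology binary geology [raster_grid] on the same grid.
#' @return a [raster_grid] of suitability in `[0, 1]`.
#' @export
true_suitability <- function(truth, pc1, pc2, geology) {
  stop_if_incongruent(pc1, pc2)
  stop_if_incongruent(pc1, geology)
  z1 <- (pc1$values - truth$niche_center[1]) / truth$niche_breadth[1]
  z2 <- (pc2$values - truth$niche_center[2]) / truth$niche_breadth[2]
  s <- exp(-0.5 * (z1^2 + z2^2)) * (geology$values > 0)
  raster_grid(s, xmin = pc1$xmin, ymax = pc1$ymax, cell = pc1$cell)
}

#' Binarised ground-truth range
#'
#' Cells whose true suitability reaches the `1 - prevalence` landscape
#' quantile, i.e. the top `prevalence` fraction of cells.
#'
#' @param truth a [species_truth].
#' @param suitability the [true_suitability()] raster.
#' @return a binary [raster_grid].
#' @export
true_suitable_area <- function(truth, suitability) {
  v <- suitability$values
  thr <- quantile(v[!is.na(v)], 1 - truth$prevalence, names = FALSE)
  raster_map(function(x) as.numeric(x >= thr & x > 0), suitability)
}

#' Sample occurrences of a virtual species
#'
#' Cells are drawn without replacement with probability proportional to the
#' true suitability; returned coordinates are cell centres.
#'
#' @inheritParams true_suitability
#' @param seed integer seed.
#' @return data frame with columns `species`, `x`, `y`.
#' @export
make_species <- function(truth, pc1, pc2, geology, seed) {
  suit <- true_suitability(truth, pc1, pc2, geology)
  w <- as.vector(suit$values)
  w[is.na(w)] <- 0
  if (sum(w) == 0) stop("empty niche on landscape")
  n_pos <- sum(w > 0)
  n <- min(truth$n_occurrences, n_pos)
  idx <- with_seed(fan_seed(seed, "species", truth$species_id), {
    sample.int(length(w), size = n, prob = w, replace = FALSE)
  })
  d <- dim(suit$values)
  row <- (idx - 1L) %% d[1] + 1L
  col <- (idx - 1L) %/% d[1] + 1L
  data.frame(
    species = truth$species_id,
    x = suit$xmin + (col - 0.5) * suit$cell,
    y = suit$ymax - (row - 0.5) * suit$cell
  )
}

#' Thin occurrences to one point per grid cell
#'
#' Mitigates pseudo-replication by keeping, within each grid cell, only the
#' first occurrence in input order (a deterministic rule).
#'
#' @param points data frame with columns `x`, `y` (and optionally
#'   `species`; thinning is then applied per species).
#' @param grid a [raster_grid] defining the cells.
#' @return the thinned data frame.
#' @export
thin_occurrences <- function(points, grid) {
  if (nrow(points) == 0L) return(points)
  idx <- cell_of(grid, points$x, points$y)
  if (anyNA(idx$row)) stop("some points fall outside the grid extent")
  key <- paste(idx$row, idx$col)
  if (!is.null(points$species)) key <- paste(points$species, key)
  points[!duplicated(key), , drop = FALSE]
}
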