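#' Nearest-neighbour resampling between grid resolutions
#'
#' Each output cell takes the value of the source cell whose centre is
#' nearest to the output cell centre.  The target cell size must be an
#' integer multiple or an integer divisor of the source cell size.
#'
#' @param dem a [raster_grid].
#' @param target_cell_m target cell size in metres.
#' @return a [raster_grid] covering the same extent at `target_cell_m`.
#' @export
resample_nearest <- function(dem, target_cell_m) {
  s <- dem$cell
  ratio <- target_cell_m / s
  ok <- isTRUE(all.equal(ratio, round(ratio))) ||
    isTRUE(all.equal(1 / ratio, round(1 / ratio)))
  if (!ok) stop("target cell must be an integer multiple or divisor of the source cell")
  d <- dim(dem$values)
  nro <- round(d[1] * s / target_cell_m)
  nco <- round(d[2] * s / target_cell_m)
  if (nro < 1 || nco < 1) stop("target resolution coarser than the raster extent")
  # source index of each output cell centre (half-open cell rule)
  src_row <- pmin(floor((seq_len(nro) - 0.5) * ratio) + 1L, d[1])
  src_col <- pmin(floor((seq_len(nco) - 0.5) * ratio) + 1L, d[2])
  raster_grid(dem$values[src_row, src_col, drop = FALSE],
              xmin = dem$xmin, ymax = dem$ymax, cell = target_cell_m)
}

#' Slope and aspect by Horn's method
#'
#' Finite differences over the 8-neighbourhood (Horn 1981, the default of
#' the classical `terrain()` raster function).  Slope is returned in
#' radians; aspect is the direction the slope faces (downhill), in radians
#' clockwise from north, with flat cells set to 0 by convention and flagged
#' in the `"flat"` attribute of the aspect raster.  Border cells are nodata.
#'
#' @param dem a [raster_grid] of at least 3 x 3 cells.
#' @return list with [raster_grid] elements `slope` and `aspect`.
#' @export
slope_aspect <- function(dem) {
  d <- dim(dem$values)
  if (d[1] < 3L || d[2] < 3L) stop("DEM must have at least 3 x 3 cells")
  z <- dem$values
  s8 <- 8 * dem$cell
  NW <- shift_matrix(z, -1L, -1L); N <- shift_matrix(z, -1L, 0L)
  NE <- shift_matrix(z, -1L, 1L);  W <- shift_matrix(z, 0L, -1L)
  E  <- shift_matrix(z, 0L, 1L);   SW <- shift_matrix(z, 1L, -1L)
  S  <- shift_matrix(z, 1L, 0L);   SE <- shift_matrix(z, 1L, 1L)
  dzdx <- ((NE + 2 * E + SE) - (NW + 2 * W + SW)) / s8
  dzdy <- ((NW + 2 * N + NE) - (SW + 2 * S + SE)) / s8  # y increases northward
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  flat <- !is.na(slope) & slope == 0
  aspect <- atan2(-dzdx, -dzdy) %% (2 * pi)  # downslope direction, cw from north
  aspect[flat] <- 0
  mk <- function(m) raster_grid(m, xmin = dem$xmin, ymax = dem$ymax, cell = dem$cell)
  asp <- mk(aspect)
  attr(asp, "flat") <- flat
  list(slope = mk(slope), aspect = asp)
}

#' Northness and eastness of an aspect raster
#'
#' @param aspect aspect [raster_grid] in radians (0 = north, clockwise).
#' @return list with rasters `northness` (`cos(aspect)`) and `eastness`
#'   (`sin(aspect)`); nodata propagates.
#' @export
northness_eastness <- function(aspect) {
  list(northness = raster_map(cos, aspect),
       eastness = raster_map(sin, aspect))
}

# All eight (row, col) neighbour offsets.
.neigh8 <- cbind(di = rep(-1:1, times = 3), dj = rep(-1:1, each = 3))[-5, ]

#' Terrain ruggedness index
#'
#' Mean absolute elevation difference between a cell and its eight
#' neighbours.  Edge and corner cells use their available neighbours (5 or
#' 3), keeping the index defined over the whole grid.
#'
#' @param dem a [raster_grid] of at least 3 x 3 cells.
#' @return a [raster_grid], same units as the DEM.
#' @export
tri <- function(dem) {
  d <- dim(dem$values)
  if (d[1] < 3L || d[2] < 3L) stop("DEM must have at least 3 x 3 cells")
  z <- dem$values
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (k in seq_len(nrow(.neigh8))) {
    nb <- shift_matrix(z, .neigh8[k, 1], .neigh8[k, 2])
    ok <- !is.na(nb)
    acc[ok] <- acc[ok] + abs(z[ok] - nb[ok])
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[is.na(z) | cnt == 0L] <- NA_real_
  raster_grid(out, xmin = dem$xmin, ymax = dem$ymax, cell = dem$cell)
}

#' Topographic complexity index
#'
#' Ratio of true (slope-corrected) 3-D surface area to planimetric 2-D area
#' within each coarse cell, computed from a finer DEM:
#' `TCI = sum_fine(A_fine / cos(slope_fine)) / A_coarse >= 1`.
#' Fine-grid border cells (whose Horn slope is undefined) are excluded from
#' the within-block mean.
#'
#' @param dem_fine fine-resolution [raster_grid] DEM.
#' @param coarse_cell_m coarse cell size; must be an integer multiple of the
#'   fine cell size (classically 10 m fine within 50 m coarse).
#' @return a [raster_grid] of TCI values on the coarse grid.
#' @export
tci <- function(dem_fine, coarse_cell_m) {
  f <- coarse_cell_m / dem_fine$cell
  if (!isTRUE(all.equal(f, round(f))) || f < 1)
    stop("coarse cell must be an integer multiple of the fine cell")
  slope <- slope_aspect(dem_fine)$slope$values
  sec <- 1 / cos(slope)
  if (any(is.infinite(sec), na.rm = TRUE)) {
    warning("vertical fine cells (slope = pi/2) excluded from TCI")
    sec[is.infinite(sec)] <- NA_real_
  }
  r <- raster_grid(sec, xmin = dem_fine$xmin, ymax = dem_fine$ymax,
                   cell = dem_fine$cell)
  block_aggregate(r, as.integer(round(f)), fun = mean, na.rm = TRUE)
}

#' Clear-sky irradiation proxy
#'
#' Deterministic stand-in for a direct-normal-irradiation layer: beam
#' incidence on each cell at equinox solar noon for the given latitude, so
#' south-facing slopes receive more than north-facing ones in the northern
#' hemisphere.  Output is strictly positive (diffuse floor) in kWh/m2.
#'
#' @param slope,aspect terrain rasters in radians ([slope_aspect()]
#'   conventions).
#' @param latitude_deg site latitude in degrees.
#' @param dni_max clear-sky maximum, kWh/m2.
#' @return a [raster_grid].
#' @export
dni_proxy <- function(slope, aspect, latitude_deg = 46, dni_max = 1800) {
  stop_if_incongruent(slope, aspect)
  h <- (90 - latitude_deg) * pi / 180  # solar elevation at equinox noon
  incidence <- raster_map(function(s, a) {
    pmax(cos(s) * sin(h) - sin(s) * cos(a) * cos(h), 0.05)
  }, slope, aspect)
  raster_map(function(x) dni_max * x, incidence)
}

#' Compute the full topographic predictor stack
#'
#' Convenience wrapper producing the five downscaling predictors plus the
#' heterogeneity indices from one DEM.
#'
#' @param dem a [raster_grid].
#' @param latitude_deg latitude for [dni_proxy()].
#' @return list of rasters: `elevation`, `slope`, `aspect`, `northness`,
#'   `eastness`, `dni`, `tri`.
#' @export
terrain_stack <- function(dem, latitude_deg = 46) {
  sa <- slope_aspect(dem)
  ne <- northness_eastness(sa$aspect)
  list(elevation = dem, slope = sa$slope, aspect = sa$aspect,
       northness = ne$northness, eastness = ne$eastness,
       dni = dni_proxy(sa$slope, sa$aspect, latitude_deg),
       tri = tri(dem))
}
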