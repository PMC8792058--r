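#' Shared climate-bin edges over pooled axis ranges
#'
#' Equal-width 2-D binning of the (PC1, PC2) plane over the pooled value
#' range of all supplied rasters, so baseline and future climates are
#' classified with identical edges.
#'
#' @param axis_pairs list of `list(pc1 = , pc2 = )` raster pairs.
#' @param shape integer pair: bins along PC1 and PC2 (default 12 x 10 =
#'   120 unique-climate classes).
#' @return list with `breaks1`, `breaks2`, `shape`, `n_bins`.
#' @export
climate_bin_breaks <- function(axis_pairs, shape = c(12L, 10L)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  rng <- function(which_axis) {
    range(unlist(lapply(axis_pairs, function(p)
      range(p[[which_axis]]$values, na.rm = TRUE))))
  }
  edges <- function(r, k) {
    if (diff(r) <= 0) {
      warning("degenerate axis range; a single bin is used on that axis")
      return(c(r[1] - 0.5, r[1] + 0.5))
    }
    seq(r[1], r[2], length.out = k + 1L)
  }
  b1 <- edges(rng("pc1"), shape[1])
  b2 <- edges(rng("pc2"), shape[2])
  list(breaks1 = b1, breaks2 = b2,
       shape = c(length(b1) - 1L, length(b2) - 1L),
       n_bins = (length(b1) - 1L) * (length(b2) - 1L))
}

#' Classify cells into unique-climate bins
#'
#' Assigns every cell a flattened class id in `[0, n_bins - 1]` from the
#' 2-D equal-width binning of its (PC1, PC2) values.  If `breaks` is not
#' supplied the edges are computed from the two rasters themselves; pass
#' pooled [climate_bin_breaks()] to share edges across scenarios.
#'
#' @param pc1,pc2 congruent axis rasters.
#' @param n_bins total number of classes when `breaks` is computed here.
#' @param shape bin-grid shape (defaults to 12 x 10 when `n_bins` is 120,
#'   otherwise near-square factorisation).
#' @param breaks optional result of [climate_bin_breaks()].
#' @return list of class `climate_binning`: `classes` (integer class
#'   raster), `breaks`.
#' @export
bin_climate <- function(pc1, pc2, n_bins = 120L, shape = NULL, breaks = NULL) {
  stop_if_incongruent(pc1, pc2)
  if (is.null(breaks)) {
    if (is.null(shape)) {
      shape <- if (n_bins == 120L) c(12L, 10L) else {
        k <- floor(sqrt(n_bins))
        while (n_bins %% k != 0L) k <- k - 1L
        c(n_bins %/% k, k)
      }
    }
    breaks <- climate_bin_breaks(list(list(pc1 = pc1, pc2 = pc2)), shape)
  }
  cut_idx <- function(v, edges) {
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    i[!is.na(i) & i < 1L] <- 1L
    i[!is.na(i) & i > length(edges) - 1L] <- length(edges) - 1L
    i
  }
  i1 <- cut_idx(pc1$values, breaks$breaks1)
  i2 <- cut_idx(pc2$values, breaks$breaks2)
  cls <- (i1 - 1L) * breaks$shape[2] + (i2 - 1L)
  structure(list(
    classes = raster_grid(matrix(as.numeric(cls), nrow(pc1$values)),
                          xmin = pc1$xmin, ymax = pc1$ymax, cell = pc1$cell),
    breaks = breaks), class = "climate_binning")
}

#' Minimum distance to the nearest analogous future climate
#'
#' For every cell with baseline class `c`, the minimum Euclidean distance
#' (cell centre to cell centre, metres) to any cell whose future class is
#' also `c`.  Cells whose own future class matches get distance 0.  Classes
#' absent from the future map are flagged as no-analog (`NA` distance; see
#' the `"no_analog"` attribute).  Backed by an exact Euclidean distance
#' transform per class.
#'
#' @param class_baseline,class_future congruent integer class rasters (from
#'   [bin_climate()]; `$classes` is also accepted).
#' @return distance [raster_grid] in metres with logical attribute
#'   `"no_analog"`.
#' @export
nearest_analog_distance <- function(class_baseline, class_future) {
  if (inherits(class_baseline, "climate_binning")) class_baseline <- class_baseline$classes
  if (inherits(class_future, "climate_binning")) class_future <- class_future$classes
  stop_if_incongruent(class_baseline, class_future)
  b <- class_baseline$values
  f <- class_future$values
  if (length(b) == 0L) stop("empty rasters")
  out <- matrix(NA_real_, nrow(b), ncol(b))
  no_analog <- matrix(FALSE, nrow(b), ncol(b))
  for (cl in sort(unique(b[!is.na(b)]))) {
    sel <- !is.na(b) & b == cl
    feat <- !is.na(f) & f == cl
    if (!any(feat)) {
      no_analog[sel] <- TRUE
      next
    }
    d2 <- edt_squared(feat)
    out[sel] <- sqrt(d2[sel]) * class_baseline$cell
  }
  res <- raster_grid(out, xmin = class_baseline$xmin,
                     ymax = class_baseline$ymax, cell = class_baseline$cell)
  attr(res, "no_analog") <- no_analog
  res
}

#' Climate-change velocity on the CCV log scale
#'
#' Velocity is the analog distance divided by the elapsed years, floored at
#' half a cell width per time span so that zero-distance cells stay finite
#' on the log scale; `CCV = 100 * log10(velocity in m/yr)`.
#'
#' @param distance_m distance [raster_grid] (metres).
#' @param delta_years elapsed years between climate periods (> 0); the
#'   default 74 spans the 1979-2013 baseline midpoint to the 2061-2080
#'   projection midpoint (75 is the commonly quoted round figure).
#' @param floor_m minimum distance; default half a cell width.
#' @return CCV [raster_grid]; the velocity raster (m/yr) is attached as
#'   attribute `"velocity"`.
#' @export
ccv_transform <- function(distance_m, delta_years = 74, floor_m = NULL) {
  if (delta_years <= 0) stop("`delta_years` must be positive")
  if (is.null(floor_m)) floor_m <- distance_m$cell / 2
  velocity <- raster_map(function(d) pmax(d, floor_m) / delta_years, distance_m)
  ccv <- raster_map(function(v) 100 * log10(v), velocity)
  attr(ccv, "velocity") <- velocity
  ccv
}

#' Average CCV surfaces over GCMs
#'
#' Cell-wise arithmetic mean on the CCV (log) scale; no-analog (`NA`) cells
#' are excluded from the mean and flagged only where every GCM lacks an
#' analog.
#'
#' @param ccv_list list of congruent CCV rasters, one per GCM.
#' @return mean CCV [raster_grid] with logical attribute `"no_analog"`.
#' @export
average_over_gcms <- function(ccv_list) {
  if (length(ccv_list) < 1L) stop("need at least one GCM surface")
  ref <- ccv_list[[1]]
  for (r in ccv_list[-1]) stop_if_incongruent(ref, r)
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  cnt <- matrix(0L, nrow(ref$values), ncol(ref$values))
  for (r in ccv_list) {
    ok <- !is.na(r$values)
    acc[ok] <- acc[ok] + r$values[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  res <- raster_grid(out, xmin = ref$xmin, ymax = ref$ymax, cell = ref$cell)
  attr(res, "no_analog") <- cnt == 0L
  res
}
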