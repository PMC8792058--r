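#' Georeferenced single-band raster grid
#'
#' The universal currency of the pipeline: a numeric matrix on a regular
#' square grid in projected (metric) coordinates.  Row 1 is the top
#' (northernmost) row; cell `(1, 1)` is the top-left cell.  `NA` values are
#' nodata.  A point belongs to the half-open cell
#' `[xmin + j*cell, xmin + (j+1)*cell)` x `(ymax - (i+1)*cell, ymax - i*cell]`
#' (0-based `i`, `j`).
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin x coordinate of the left (west) edge, metres.
#' @param ymax y coordinate of the top (north) edge, metres.
#' @param cell cell side length, metres (> 0).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * cell, cell = 1) {
  if (!is.matrix(values) || !is.numeric(values[1]) && !is.logical(values[1]))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell) || length(cell) != 1L || cell <= 0)
    stop("`cell` must be a single positive number")
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cell = as.numeric(cell)),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells @ %g m\n", d[1], d[2], x$cell))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + d[2] * x$cell, x$ymax - d[1] * x$cell, x$ymax))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata\n", min(v), max(v),
                sum(is.na(x$values))))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
plot.raster_grid <- function(x, main = "", ...) {
  d <- dim(x$values)
  xs <- x$xmin + (seq_len(d[2]) - 0.5) * x$cell
  ys <- x$ymax - (rev(seq_len(d[1])) - 0.5) * x$cell
  image(xs, ys, t(x$values[d[1]:1, , drop = FALSE]), asp = 1,
        xlab = "x (m)", ylab = "y (m)", main = main, ...)
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param r a [raster_grid].
#' @return data frame with `x`, `y`, `row`, `col`, `value` for every cell
#'   (column-major order).
#' @export
grid_coordinates <- function(r) {
  d <- dim(r$values)
  row <- rep(seq_len(d[1]), times = d[2])
  col <- rep(seq_len(d[2]), each = d[1])
  data.frame(
    x = r$xmin + (col - 0.5) * r$cell,
    y = r$ymax - (row - 0.5) * r$cell,
    row = row, col = col,
    value = as.vector(r$values)
  )
}

#' Locate points on a grid
#'
#' Maps point coordinates to 1-based row/col indices under the half-open
#' cell convention.  Points outside the extent get `NA` indices.
#'
#' @param r a [raster_grid].
#' @param x,y point coordinates (metres).
#' @return data frame with columns `row`, `col`.
#' @export
cell_of <- function(r, x, y) {
  d <- dim(r$values)
  col <- floor((x - r$xmin) / r$cell) + 1
  row <- floor((r$ymax - y) / r$cell) + 1
  # points exactly on the top/left edge belong to the first cell
  row[y == r$ymax] <- 1
  bad <- row < 1 | row > d[1] | col < 1 | col > d[2]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @inheritParams cell_of
#' @return numeric vector (NA outside the extent / at nodata cells).
#' @export
extract_values <- function(r, x, y) {
  idx <- cell_of(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- r$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Test two rasters for grid congruence
#'
#' @param a,b [raster_grid] objects.
#' @param tol coordinate tolerance in metres.
#' @return `TRUE`/`FALSE`.
#' @export
grids_congruent <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cell - b$cell) < tol
}

stop_if_incongruent <- function(a, b) {
  if (!grids_congruent(a, b)) stop("rasters are not on congruent grids")
  invisible(TRUE)
}

#' Block-aggregate a raster to a coarser grid
#'
#' Aggregates `factor` x `factor` blocks of fine cells into one coarse cell.
#'
#' @param r a [raster_grid] whose dimensions are divisible by `factor`.
#' @param factor integer block side (fine cells per coarse cell side).
#' @param fun summary function applied per block (default mean).
#' @param na.rm passed to `fun`.
#' @return a [raster_grid] with cell size `factor * r$cell`.
#' @export
block_aggregate <- function(r, factor, fun = mean, na.rm = TRUE) {
  d <- dim(r$values)
  factor <- as.integer(factor)
  if (factor < 1L || d[1] %% factor != 0L || d[2] %% factor != 0L)
    stop("raster dimensions must be divisible by the aggregation factor")
  nrb <- d[1] %/% factor
  ncb <- d[2] %/% factor
  a <- array(r$values, c(factor, nrb, factor, ncb))
  out <- apply(a, c(2L, 4L), fun, na.rm = na.rm)
  out[is.nan(out)] <- NA_real_
  raster_grid(out, xmin = r$xmin, ymax = r$ymax, cell = r$cell * factor)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`.asc`): a 6-line header followed by the
#' value matrix, top row first.
#'
#' @param r a [raster_grid].
#' @param path file path.
#' @param digits significant digits written.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a [raster_grid].
#' @export
write_ascii_grid <- function(r, path, digits = 10) {
  d <- dim(r$values)
  nodata <- -9999
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", d[2]),
    sprintf("NROWS %d", d[1]),
    sprintf("XLLCORNER %.10g", r$xmin),
    sprintf("YLLCORNER %.10g", r$ymax - d[1] * r$cell),
    sprintf("CELLSIZE %.10g", r$cell),
    sprintf("NODATA_VALUE %d", nodata)
  ), con)
  writeLines(apply(format(v, digits = digits, trim = TRUE, scientific = FALSE),
                   1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- toupper(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (nrow(m) != vals[["NROWS"]] || ncol(m) != vals[["NCOLS"]])
    stop("ASCII grid body does not match its header")
  m[m == vals[["NODATA_VALUE"]]] <- NA_real_
  raster_grid(m,
              xmin = vals[["XLLCORNER"]],
              ymax = vals[["YLLCORNER"]] + vals[["NROWS"]] * vals[["CELLSIZE"]],
              cell = vals[["CELLSIZE"]])
}

#' Apply a function cell-wise to one or more congruent rasters
#'
#' @param f vectorised function of the value matrices.
#' @param ... [raster_grid] objects on one grid.
#' @return a [raster_grid].
#' @export
raster_map <- function(f, ...) {
  rs <- list(...)
  for (r in rs[-1]) stop_if_incongruent(rs[[1]], r)
  out <- do.call(f, lapply(rs, `[[`, "values"))
  raster_grid(matrix(out, nrow(rs[[1]]$values)),
              xmin = rs[[1]]$xmin, ymax = rs[[1]]$ymax, cell = rs[[1]]$cell)
}
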