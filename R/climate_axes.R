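#' Pooled principal-component climate axes
#'
#' Fits one PCA on the 19 bioclimatic variables of all scenarios pooled
#' together (cells x scenarios row-stacked, standardised), then projects
#' each scenario with the shared loadings so that baseline and future
#' climates live on one common pair of axes.  Layers constant across the
#' pool are dropped with a warning.  Axis signs are fixed deterministically:
#' PC1 is oriented to correlate positively with the mean of the
#' temperature-like layers, PC2 so its largest-magnitude loading is
#' positive.
#'
#' @param scenarios list of `climate_scenario` objects (see
#'   [make_bioclim()]) sharing one coarse grid.
#' @param temp_layers names of the temperature-like layers used to orient
#'   PC1 (default `bio01`-`bio11`, the usual convention).
#' @return An object of class `pooled_pca`: `loadings` (variables x 2),
#'   `explained_variance` (length-2 fractions), `center`, `scale`,
#'   `per_scenario_axes` (per tag: list of rasters `pc1`, `pc2`).
#' @export
pooled_pca <- function(scenarios, temp_layers = temperature_like_layers()) {
  stopifnot(length(scenarios) >= 1L)
  ref <- scenarios[[1]]$layers[[1]]
  layer_names <- names(scenarios[[1]]$layers)
  for (sc in scenarios)
    for (l in sc$layers) stop_if_incongruent(ref, l)

  stack_one <- function(sc)
    do.call(cbind, lapply(sc$layers, function(r) as.vector(r$values)))
  X <- do.call(rbind, lapply(scenarios, stack_one))
  colnames(X) <- layer_names
  keep <- apply(X, 2L, function(v) sd(v, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning("dropping constant layer(s): ", paste(layer_names[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("fewer than two non-constant layers; cannot build two axes")

  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  load2 <- pca$rotation[, 1:2, drop = FALSE]
  ev <- pca$sdev^2 / sum(pca$sdev^2)

  # deterministic sign conventions
  tcols <- intersect(temp_layers, colnames(X))
  if (length(tcols)) {
    tmean <- rowMeans(scale(X[, tcols, drop = FALSE]))
    if (cor(pca$x[, 1], tmean) < 0) load2[, 1] <- -load2[, 1]
  }
  if (load2[which.max(abs(load2[, 2])), 2] < 0) load2[, 2] <- -load2[, 2]

  res <- structure(
    list(loadings = load2, explained_variance = ev[1:2],
         center = pca$center, scale = pca$scale,
         per_scenario_axes = NULL),
    class = "pooled_pca")
  res$per_scenario_axes <- lapply(scenarios, function(sc) project_scenario(res, sc))
  names(res$per_scenario_axes) <- vapply(scenarios, `[[`, "", "tag")
  res
}

#' Project a climate scenario onto fitted pooled axes
#'
#' @param pca a [pooled_pca()] result.
#' @param scenario a `climate_scenario`.
#' @return list of rasters `pc1`, `pc2`.
#' @export
project_scenario <- function(pca, scenario) {
  vars <- rownames(pca$loadings)
  ref <- scenario$layers[[1]]
  X <- do.call(cbind, lapply(scenario$layers[vars],
                             function(r) as.vector(r$values)))
  Xs <- sweep(sweep(X, 2L, pca$center), 2L, pca$scale, `/`)
  sc <- Xs %*% pca$loadings
  d <- dim(ref$values)
  mk <- function(v) raster_grid(matrix(v, d[1], d[2]), xmin = ref$xmin,
                                ymax = ref$ymax, cell = ref$cell)
  list(pc1 = mk(sc[, 1]), pc2 = mk(sc[, 2]))
}

#' Downscale a coarse climate axis by geographically weighted regression
#'
#' At each coarse cell a locally weighted linear regression of the axis on
#' five coarse-aggregated topographic predictors (elevation, slope,
#' northness, eastness, irradiation) is fitted with a Gaussian
#' distance-decay kernel; the local coefficients are then applied to the
#' fine-grid predictor values of the fine cells inside that coarse cell.
#' Predictors are standardised by their coarse-grid moments for numerical
#' conditioning.  A rank-deficient local design (e.g. flat terrain within
#' the bandwidth) falls back to the kernel-weighted local mean with a
#' warning.
#'
#' @param axis_coarse coarse [raster_grid] of axis values.
#' @param terrain_fine list of fine rasters with elements `elevation`,
#'   `slope`, `northness`, `eastness`, `dni` (see [terrain_stack()]).
#' @param bandwidth_m Gaussian kernel bandwidth in metres; default 3 coarse
#'   cell widths.
#' @return the downscaled fine [raster_grid]; the per-coarse-cell
#'   coefficients are attached as attribute `"gwr"`.
#' @export
gwr_downscale <- function(axis_coarse, terrain_fine, bandwidth_m = NULL) {
  preds <- c("elevation", "slope", "northness", "eastness", "dni")
  if (!all(preds %in% names(terrain_fine)))
    stop("`terrain_fine` must provide: ", paste(preds, collapse = ", "))
  fine_ref <- terrain_fine$elevation
  f <- axis_coarse$cell / fine_ref$cell
  if (!isTRUE(all.equal(f, round(f))))
    stop("coarse cell must be an integer multiple of the fine cell")
  f <- as.integer(round(f))
  if (is.null(bandwidth_m)) bandwidth_m <- 3 * axis_coarse$cell
  if (bandwidth_m <= 0) stop("`bandwidth_m` must be positive")

  coarse_pred <- lapply(terrain_fine[preds], block_aggregate, factor = f)
  dc <- dim(axis_coarse$values)
  Xc <- do.call(cbind, lapply(coarse_pred, function(r) as.vector(r$values)))
  y <- as.vector(axis_coarse$values)
  cc <- grid_coordinates(axis_coarse)

  # standardise predictors on the coarse sample
  mu <- colMeans(Xc, na.rm = TRUE)
  sg <- apply(Xc, 2L, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  Xs <- sweep(sweep(Xc, 2L, mu), 2L, sg, `/`)

  n <- length(y)
  p <- ncol(Xs) + 1L
  beta <- matrix(NA_real_, n, p)
  fallback <- 0L
  usable <- !is.na(y) & complete.cases(Xs)
  for (i in which(usable)) {
    dist2 <- (cc$x - cc$x[i])^2 + (cc$y - cc$y[i])^2
    w <- exp(-0.5 * dist2 / bandwidth_m^2)
    w[!usable] <- 0
    Xi <- cbind(1, Xs)
    sw <- sqrt(w)
    qr_i <- qr(Xi * sw)
    if (qr_i$rank < p) {
      beta[i, ] <- c(sum(w * y, na.rm = TRUE) / sum(w), rep(0, p - 1L))
      fallback <- fallback + 1L
    } else {
      beta[i, ] <- qr.coef(qr_i, y * sw)
    }
  }
  if (fallback > 0L)
    warning(fallback, " coarse cell(s) had a rank-deficient local design; ",
            "intercept-only fallback used")

  # fine prediction: each fine cell uses its parent coarse cell's coefficients
  df <- dim(fine_ref$values)
  Xf <- do.call(cbind, lapply(terrain_fine[preds], function(r) as.vector(r$values)))
  Xfs <- cbind(1, sweep(sweep(Xf, 2L, mu), 2L, sg, `/`))
  fr <- rep(seq_len(df[1]), times = df[2])
  fc <- rep(seq_len(df[2]), each = df[1])
  parent <- ((fc - 1L) %/% f) * dc[1] + ((fr - 1L) %/% f) + 1L  # column-major
  pred <- rowSums(Xfs * beta[parent, , drop = FALSE])
  out <- raster_grid(matrix(pred, df[1], df[2]), xmin = fine_ref$xmin,
                     ymax = fine_ref$ymax, cell = fine_ref$cell)
  attr(out, "gwr") <- list(coefficients = beta, bandwidth_m = bandwidth_m,
                           center = mu, scale = sg, fallback_cells = fallback)
  out
}
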