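#' ROC threshold selection methods
#'
#' @return character vector of the three supported cutoff rules.
#' @export
threshold_methods <- function()
  c("equal_sens_spec", "max_sens_spec", "min_roc_distance")

#' Select a binarization cutoff from scores and labels
#'
#' Candidate cutoffs are the distinct observed scores plus 0 and 1.  The
#' three rules: `equal_sens_spec` minimises `|sensitivity - specificity|`;
#' `max_sens_spec` maximises `sensitivity + specificity` (max TSS);
#' `min_roc_distance` minimises the Euclidean distance of the ROC point to
#' the perfect-classifier corner (0, 1).  Among equal-optimal candidates the
#' smallest cutoff is returned (deterministic tie-break).
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary labels.
#' @param method one of [threshold_methods()].
#' @return An object of class `threshold_rule`: `method`, `cutoff`,
#'   `sensitivity`, `specificity` at the cutoff.
#' @export
find_cutoff <- function(scores, labels, method = threshold_methods()) {
  method <- match.arg(method)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  cand <- sort(unique(c(0, scores, 1)))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(cand, function(ct) mean(pos >= ct), 0)
  spec <- vapply(cand, function(ct) mean(neg < ct), 0)
  objective <- switch(method,
    equal_sens_spec = -abs(sens - spec),
    max_sens_spec = sens + spec,
    min_roc_distance = -sqrt((1 - sens)^2 + (1 - spec)^2))
  best <- which(objective >= max(objective) - 1e-12)
  pick <- best[which.min(cand[best])]
  structure(list(method = method, cutoff = cand[pick],
                 sensitivity = sens[pick], specificity = spec[pick]),
            class = "threshold_rule")
}

#' Binarize a continuous suitability map
#'
#' A cell is suitable (1) when its suitability is greater than or equal to
#' the cutoff (inclusive boundary rule); nodata propagates.
#'
#' @param suitability a [raster_grid] in `[0, 1]`.
#' @param rule a `threshold_rule` or a bare numeric cutoff in `[0, 1]`.
#' @return a binary [raster_grid].
#' @export
binarize <- function(suitability, rule) {
  cutoff <- if (inherits(rule, "threshold_rule")) rule$cutoff else as.numeric(rule)
  if (is.na(cutoff) || cutoff < 0 || cutoff > 1)
    stop("cutoff must be in [0, 1]")
  raster_map(function(x) as.numeric(x >= cutoff), suitability)
}

#' Projection inventory arithmetic
#'
#' Number of binary projections implied by the ensemble design: baseline
#' uses thresholds x algorithms; each future rcp additionally multiplies by
#' the number of GCMs.
#'
#' @param n_algorithms,n_thresholds,n_gcms,n_rcps positive integers.
#' @return list with `baseline`, `per_rcp`, `total` counts.
#' @export
enumerate_projections <- function(n_algorithms, n_thresholds, n_gcms, n_rcps) {
  stopifnot(n_algorithms >= 1, n_thresholds >= 1, n_gcms >= 1, n_rcps >= 1)
  baseline <- n_thresholds * n_algorithms
  per_rcp <- n_thresholds * n_algorithms * n_gcms
  list(baseline = baseline, per_rcp = per_rcp,
       total = baseline + per_rcp * n_rcps)
}

#' Majority consensus over binary projections
#'
#' A cell is declared suitable when at least 50% of the non-nodata votes
#' are 1 (a tie at exactly 50% counts as presence).
#'
#' @param projections list of congruent binary [raster_grid]s.
#' @return a binary [raster_grid]; cells with no votes are nodata.
#' @export
majority_consensus <- function(projections) {
  if (length(projections) < 1L) stop("need at least one projection")
  ref <- projections[[1]]
  for (p in projections[-1]) stop_if_incongruent(ref, p)
  ones <- matrix(0, nrow(ref$values), ncol(ref$values))
  votes <- matrix(0L, nrow(ref$values), ncol(ref$values))
  for (p in projections) {
    v <- p$values
    ok <- !is.na(v)
    ones[ok] <- ones[ok] + v[ok]
    votes <- votes + ok
  }
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  has <- votes > 0L
  out[has] <- as.numeric(ones[has] / votes[has] >= 0.5)
  raster_grid(out, xmin = ref$xmin, ymax = ref$ymax, cell = ref$cell)
}

#' Mask a consensus map by the carbonate-geology layer
#'
#' @param consensus binary [raster_grid].
#' @param mask binary geology [raster_grid] on the same grid.
#' @return binary [raster_grid]: `consensus AND mask`.
#' @export
apply_geology_mask <- function(consensus, mask) {
  stop_if_incongruent(consensus, mask)
  mv <- mask$values[!is.na(mask$values)]
  if (!all(mv %in% c(0, 1))) stop("geology mask must be binary")
  raster_map(function(c, m) as.numeric(c > 0) * as.numeric(m > 0), consensus, mask)
}
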