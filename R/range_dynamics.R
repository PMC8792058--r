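#' Range-change cell categories
#'
#' Integer codes used in category maps.
#'
#' @return named integer vector: `unsuitable` = 0, `loss` = 1,
#'   `stable` = 2, `gain` = 3.
#' @export
range_categories <- function()
  c(unsuitable = 0L, loss = 1L, stable = 2L, gain = 3L)

#' Classify cells by baseline-to-future transition
#'
#' Suitable only under baseline = loss; suitable only under future = gain;
#' suitable under both = stable; suitable under neither = unsuitable.
#'
#' @param baseline,future congruent binary [raster_grid]s.
#' @return a [raster_grid] of [range_categories()] codes.
#' @export
classify_cells <- function(baseline, future) {
  stop_if_incongruent(baseline, future)
  chk <- function(r) {
    v <- r$values[!is.na(r$values)]
    if (!all(v %in% c(0, 1))) stop("input rasters must be binary")
  }
  chk(baseline); chk(future)
  raster_map(function(b, f) {
    b <- b > 0; f <- f > 0
    out <- rep(NA_real_, length(b))
    out[!b & !f] <- 0; out[b & !f] <- 1; out[b & f] <- 2; out[!b & f] <- 3
    out
  }, baseline, future)
}

#' Count cells per range-change category
#'
#' @param category_map output of [classify_cells()].
#' @return named integer vector over [range_categories()] names, plus `PR`
#'   (present range = loss + stable), `RL` and `RG` counts.
#' @export
count_categories <- function(category_map) {
  v <- category_map$values
  cats <- range_categories()
  n <- vapply(cats, function(code) sum(v == code, na.rm = TRUE), 0L)
  c(n, PR = unname(n["loss"] + n["stable"]), RL = unname(n["loss"]),
    RG = unname(n["gain"]))
}

#' Range-change percentages
#'
#' `RC = 100 * (RG - RL) / PR`; the no-dispersal readout is the percentage
#' of range lost (`RL_pct = 100 * RL / PR`), the full-dispersal readout the
#' overall change `RC`.  `RG_pct = 100 * RG / PR`.
#'
#' @param PR present (baseline) range size in cells (> 0).
#' @param RL,RG lost and gained cell counts.
#' @return list with `rc_pct`, `rl_pct`, `rg_pct`.
#' @export
range_change <- function(PR, RL, RG) {
  if (is.na(PR) || PR <= 0) stop("species has no baseline range")
  list(rc_pct = 100 * (RG - RL) / PR,
       rl_pct = 100 * RL / PR,
       rg_pct = 100 * RG / PR)
}

#' Range change of one baseline/future map pair
#'
#' @param baseline,future congruent binary [raster_grid]s.
#' @return list: `counts` (from [count_categories()]), `rc_pct`, `rl_pct`,
#'   `rg_pct`, and the `category_map`.
#' @export
range_change_maps <- function(baseline, future) {
  cm <- classify_cells(baseline, future)
  n <- count_categories(cm)
  rc <- range_change(n[["PR"]], n[["RL"]], n[["RG"]])
  c(list(counts = n, category_map = cm), rc)
}

#' Summarise range metrics across ensemble combinations
#'
#' Sample mean and standard deviation (n - 1 denominator; 0 for a single
#' combination) of RC/RL/RG percentages across algorithm x GCM x threshold
#' combinations.
#'
#' @param combos data frame with columns `rc_pct`, `rl_pct`, `rg_pct` (one
#'   row per combination).
#' @return data frame with columns `metric`, `mean`, `sd`.
#' @export
summarize_combinations <- function(combos) {
  if (nrow(combos) < 1L) stop("need at least one combination")
  one <- function(v) c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0)
  m <- vapply(combos[c("rc_pct", "rl_pct", "rg_pct")], one, c(mean = 0, sd = 0))
  data.frame(metric = c("rc_pct", "rl_pct", "rg_pct"),
             mean = m["mean", ], sd = m["sd", ], row.names = NULL)
}
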