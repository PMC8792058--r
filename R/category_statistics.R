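#' Build the per-cell covariate table for one species/scenario
#'
#' One row per loss/stable/gain cell (unsuitable cells are excluded) with
#' the covariates compared among categories.
#'
#' @param category_map a [classify_cells()] raster.
#' @param covariates named list of congruent rasters (e.g. `elevation`,
#'   `tri`, `tci`, `ccv_rcp45`, `ccv_rcp85`).
#' @param complete_only drop rows with any missing covariate (default).
#' @return data frame with `category` (factor loss/stable/gain) plus one
#'   column per covariate.
#' @export
build_cell_table <- function(category_map, covariates, complete_only = TRUE) {
  stopifnot(length(covariates) >= 1L, !is.null(names(covariates)))
  for (r in covariates) stop_if_incongruent(category_map, r)
  code <- as.vector(category_map$values)
  keep <- !is.na(code) & code %in% 1:3
  out <- data.frame(category = factor(
    c("loss", "stable", "gain")[code[keep]], levels = c("loss", "stable", "gain")))
  for (nm in names(covariates))
    out[[nm]] <- as.vector(covariates[[nm]]$values)[keep]
  if (complete_only) out <- out[complete.cases(out), , drop = FALSE]
  out
}

#' Pearson correlation matrix of landscape covariates
#'
#' @param table data frame of numeric columns (typically elevation, TCI,
#'   TRI and the two CCV surfaces over the whole study area).
#' @return symmetric correlation matrix with unit diagonal; entries against
#'   a constant column are `NA` (with a warning).
#' @export
pearson_matrix <- function(table) {
  x <- as.matrix(table[vapply(table, is.numeric, TRUE)])
  if (nrow(x) < 3L) stop("need at least 3 complete rows")
  const <- apply(x, 2L, function(v) sd(v, na.rm = TRUE) == 0)
  if (any(const))
    warning("constant column(s): ", paste(colnames(x)[const], collapse = ", "),
            "; correlations undefined")
  m <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}

#' Kruskal-Wallis test among categories
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation for the p value (the behaviour of the classical R test).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length (>= 2 non-empty
#'   groups).
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L)   # all-tie degenerate case: no evidence
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Mann-Whitney tests with multiplicity correction
#'
#' Two-sided rank-sum tests for every pair of categories, adjusted with
#' Bonferroni by default (each p multiplied by the number of comparisons
#' and capped at 1).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param correction p-adjustment method (default `"bonferroni"`).
#' @return lower-triangular matrix of adjusted p values.
#' @export
pairwise_mann_whitney <- function(values, groups, correction = "bonferroni") {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = correction))
  pw$p.value
}

#' Randomization robustness of the Kruskal-Wallis comparison
#'
#' Re-runs the category comparison on random subsamples to probe
#' sensitivity to pseudo-replication: per replicate, each category is
#' subsampled without replacement under the chosen scheme (10% of its
#' cells, 1% of its cells, or capped at 1000 cells), the Kruskal-Wallis
#' test is run per variable, and the number of significant replicates is
#' counted.  A category too small for a fractional scheme is kept whole
#' with a warning.
#'
#' @param table a [build_cell_table()] data frame.
#' @param variables which covariate columns to test (default: all numeric).
#' @param scheme `"frac_10"`, `"frac_1"` or `"cap_1000"`.
#' @param reps number of randomization replicates (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return object of class `robustness_report`: data frame `counts`
#'   (variable, n_significant, reps), plus `scheme` and `alpha`.
#' @export
randomization_robustness <- function(table, variables = NULL,
                                     scheme = c("frac_10", "frac_1", "cap_1000"),
                                     reps = 1000L, alpha = 0.05, seed = 1L) {
  scheme <- match.arg(scheme)
  if (is.null(variables))
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  groups <- droplevels(factor(table$category))
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty categories")
  idx_by_cat <- split(seq_len(nrow(table)), groups)
  frac <- switch(scheme, frac_10 = 0.10, frac_1 = 0.01, cap_1000 = NA_real_)
  take <- vapply(idx_by_cat, function(ix) {
    n <- length(ix)
    if (scheme == "cap_1000") min(n, 1000L)
    else max(as.integer(floor(frac * n)), 0L)
  }, integer(1))
  if (any(take < 1L)) {
    warning("categor(ies) ", paste(names(take)[take < 1L], collapse = ", "),
            " too small for the ", scheme, " scheme; all their cells are used")
    take[take < 1L] <- lengths(idx_by_cat)[take < 1L]
  }
  hits <- setNames(integer(length(variables)), variables)
  for (r in seq_len(reps)) {
    sel <- unlist(lapply(seq_along(idx_by_cat), function(g) {
      with_seed(fan_seed(seed, "robust", scheme, r, g),
                sample(idx_by_cat[[g]], take[g]))
    }), use.names = FALSE)
    sub <- table[sel, , drop = FALSE]
    g <- droplevels(factor(sub$category))
    for (v in variables) {
      p <- suppressWarnings(kruskal.test(sub[[v]], g)$p.value)
      if (!is.na(p) && p <= alpha) hits[v] <- hits[v] + 1L
    }
  }
  structure(list(
    counts = data.frame(variable = variables, n_significant = unname(hits),
                        reps = reps),
    scheme = scheme, alpha = alpha), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("Randomization robustness (%s, alpha = %g, %d reps)\n",
              x$scheme, x$alpha, x$counts$reps[1]))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
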