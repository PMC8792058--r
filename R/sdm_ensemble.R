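#' Supported model families
#'
#' Five classical SDM algorithm families: two regression methods
#' (`"glm"` linear-additive logistic, `"gam"` smooth-additive logistic),
#' two machine-learning methods (`"gbm"` boosted trees, `"rf"` random
#' forest) and one classification method (`"cta"` single decision tree).
#'
#' @return character vector of family codes.
#' @export
sdm_families <- function() c("glm", "gam", "gbm", "rf", "cta")

#' Specify an SDM model run
#'
#' @param pa_count pseudo-absences per replicate set; `NA` means "match the
#'   presence count", resolved when the pipeline runs.
#' @param pa_sets number of pseudo-absence replicate sets.
#' @param cv_repeats split-sample cross-validation repeats (default 10).
#' @param holdout_fraction held-out fraction per repeat (default 0.30).
#' @return An object of class `sdm_spec`.
#' @export
sdm_spec <- function(pa_count, pa_sets = 1L, cv_repeats = 10L,
                     holdout_fraction = 0.3) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("`holdout_fraction` must be in (0, 1)")
  if (cv_repeats < 1L) stop("`cv_repeats` must be >= 1")
  if (!is.na(pa_count) && pa_count < 1L) stop("`pa_count` must be >= 1")
  structure(list(pa_count = as.integer(pa_count), pa_sets = as.integer(pa_sets),
                 cv_repeats = as.integer(cv_repeats),
                 holdout_fraction = holdout_fraction),
            class = "sdm_spec")
}

#' Recommended pseudo-absence design per family
#'
#' The customary large-background recommendation: regression families use
#' many (default 10000) pseudo-absences in a few sets; tree-based families
#' use as many pseudo-absences as presences, in more sets.
#'
#' @param family one of [sdm_families()].
#' @param n_presences presence count.
#' @param cv_repeats,holdout_fraction passed through to [sdm_spec()].
#' @return an [sdm_spec()].
#' @export
default_sdm_spec <- function(family, n_presences, cv_repeats = 10L,
                             holdout_fraction = 0.3) {
  family <- match.arg(family, sdm_families())
  if (family %in% c("glm", "gam"))
    sdm_spec(10000L, pa_sets = 3L, cv_repeats = cv_repeats,
             holdout_fraction = holdout_fraction)
  else
    sdm_spec(as.integer(n_presences), pa_sets = 10L, cv_repeats = cv_repeats,
             holdout_fraction = holdout_fraction)
}

#' Sample pseudo-absence points
#'
#' Uniform draws from the non-nodata cells of the domain that contain no
#' presence, without replacement; returned coordinates are cell centres.
#' Distinct `pa_set` ids give distinct (but individually reproducible)
#' sets.
#'
#' @param domain a [raster_grid]; `NA` cells are excluded.
#' @param presences data frame with `x`, `y` of presence points.
#' @param pa_count number of pseudo-absences.
#' @param pa_set replicate-set id (integer).
#' @param seed integer seed.
#' @return data frame with columns `x`, `y`.
#' @export
sample_pseudo_absences <- function(domain, presences, pa_count, pa_set = 1L,
                                   seed = 1L) {
  d <- dim(domain$values)
  occupied <- rep(FALSE, prod(d))
  if (nrow(presences)) {
    idx <- cell_of(domain, presences$x, presences$y)
    ok <- !is.na(idx$row)
    occupied[(idx$col[ok] - 1L) * d[1] + idx$row[ok]] <- TRUE
  }
  candidates <- which(!is.na(as.vector(domain$values)) & !occupied)
  if (length(candidates) < pa_count)
    stop("domain has fewer than `pa_count` eligible cells")
  idx <- with_seed(fan_seed(seed, "pa", pa_set), {
    sample(candidates, pa_count, replace = FALSE)
  })
  row <- (idx - 1L) %% d[1] + 1L
  col <- (idx - 1L) %/% d[1] + 1L
  data.frame(x = domain$xmin + (col - 0.5) * domain$cell,
             y = domain$ymax - (row - 0.5) * domain$cell)
}

#' Fit one SDM family
#'
#' Fits the requested learner on a presence/pseudo-absence table over the
#' two climate axes.  Hyperparameters are fixed and documented: the
#' logistic regression uses linear plus quadratic terms, the additive model
#' thin-plate smooths (k = 5), boosting 100 rounds of depth-3 trees at
#' learning rate 0.1, the random forest 250 trees, the decision tree the
#' standard complexity pruning default.
#'
#' @param family one of [sdm_families()].
#' @param train data frame with numeric `pc1`, `pc2` and binary `pres`.
#' @param seed integer seed for the stochastic learners.
#' @return an object of class `sdm_fit`.
#' @export
fit_sdm <- function(family, train, seed = 1L) {
  family <- match.arg(family, sdm_families())
  if (length(unique(train$pres)) < 2L)
    stop("training data must contain both classes")
  train$pres <- as.numeric(train$pres)
  fit <- with_seed(fan_seed(seed, "fit", family), switch(
    family,
    glm = suppressWarnings(
      glm(pres ~ pc1 + I(pc1^2) + pc2 + I(pc2^2), family = binomial(),
          data = train)),
    gam = {
      k1 <- min(5L, length(unique(train$pc1)))
      k2 <- min(5L, length(unique(train$pc2)))
      if (k1 < 3L || k2 < 3L)
        suppressWarnings(glm(pres ~ pc1 + pc2, family = binomial(), data = train))
      else
        mgcv::gam(pres ~ s(pc1, k = k1) + s(pc2, k = k2), family = binomial(),
                  data = train, method = "REML")
    },
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                    nthread = 1, seed = fan_seed(seed, "xgb")),
      data = xgboost::xgb.DMatrix(as.matrix(train[, c("pc1", "pc2")]),
                                  label = train$pres, nthread = 1),
      nrounds = 100, verbose = 0),
    rf = randomForest::randomForest(
      x = train[, c("pc1", "pc2")], y = factor(train$pres, levels = c(0, 1)),
      ntree = 250),
    cta = rpart::rpart(factor(pres, levels = c(0, 1)) ~ pc1 + pc2,
                       data = train, method = "class")
  ))
  structure(list(family = family, model = fit), class = "sdm_fit")
}

#' Predict suitability from a fitted SDM
#'
#' @param object an `sdm_fit`.
#' @param newdata data frame with `pc1`, `pc2`.
#' @param ... unused.
#' @return numeric suitability in `[0, 1]` (NA rows propagate).
#' @export
predict.sdm_fit <- function(object, newdata, ...) {
  out <- rep(NA_real_, nrow(newdata))
  ok <- complete.cases(newdata[, c("pc1", "pc2")])
  nd <- newdata[ok, , drop = FALSE]
  p <- switch(object$family,
    glm = suppressWarnings(predict(object$model, nd, type = "response")),
    gam = suppressWarnings(as.numeric(predict(object$model, nd, type = "response"))),
    gbm = predict(object$model, as.matrix(nd[, c("pc1", "pc2")])),
    rf = predict(object$model, nd, type = "prob")[, "1"],
    cta = predict(object$model, nd, type = "prob")[, "1"]
  )
  out[ok] <- pmin(pmax(as.numeric(p), 0), 1)
  out
}

#' Fit a family and predict a suitability map
#'
#' @param family one of [sdm_families()].
#' @param train data frame with `pc1`, `pc2`, `pres`.
#' @param predict_stack list with fine rasters `pc1` and `pc2`.
#' @param seed integer seed.
#' @return a [raster_grid] of continuous suitability in `[0, 1]`.
#' @export
fit_predict <- function(family, train, predict_stack, seed = 1L) {
  fit <- fit_sdm(family, train, seed = seed)
  predict_suitability(fit, predict_stack)
}

#' @rdname fit_predict
#' @param fit an `sdm_fit`.
#' @export
predict_suitability <- function(fit, predict_stack) {
  stop_if_incongruent(predict_stack$pc1, predict_stack$pc2)
  ref <- predict_stack$pc1
  nd <- data.frame(pc1 = as.vector(predict_stack$pc1$values),
                   pc2 = as.vector(predict_stack$pc2$values))
  p <- predict(fit, nd)
  raster_grid(matrix(p, nrow(ref$values)), xmin = ref$xmin, ymax = ref$ymax,
              cell = ref$cell)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic with midranks for ties.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' `sensitivity + specificity - 1` from the four confusion-matrix counts.
#'
#' @param tp,fn,tn,fp confusion counts (true positive, false negative,
#'   true negative, false positive).
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0) stop("both observed classes must be present")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# Confusion counts of scores >= cutoff against binary labels.
confusion_at <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  c(tp = sum(pred & labels == 1), fn = sum(!pred & labels == 1),
    tn = sum(!pred & labels == 0), fp = sum(pred & labels == 0))
}

#' Repeated split-sample cross-validation
#'
#' For each pseudo-absence set, repeats a random 70/30 split
#' `cv_repeats` times; fits on the 70% and evaluates AUC and TSS (at the
#' max-sensitivity-plus-specificity cutoff) on the held-out 30%.  The three
#' ROC threshold cutoffs are also recorded per repeat, computed on the
#' training scores.  A split that leaves a side single-class is redrawn up
#' to 10 times, then errors.
#'
#' @param family one of [sdm_families()].
#' @param datasets a single data frame (`pc1`, `pc2`, `pres`) or a list of
#'   them, one per pseudo-absence set.
#' @param spec an [sdm_spec()].
#' @param seed integer seed.
#' @return data frame with one row per (pa_set, repeat): `family`,
#'   `pa_set`, `rep`, `auc`, `tss`, `cutoff_equal_sens_spec`,
#'   `cutoff_max_sens_spec`, `cutoff_min_roc_distance`.
#' @export
cross_validate <- function(family, datasets, spec, seed = 1L) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  out <- vector("list", length(datasets) * spec$cv_repeats)
  k <- 0L
  for (s in seq_along(datasets)) {
    data <- datasets[[s]]
    n <- nrow(data)
    n_test <- max(1L, round(spec$holdout_fraction * n))
    for (r in seq_len(spec$cv_repeats)) {
      split_seed <- fan_seed(seed, "cv", family, s, r)
      test_idx <- NULL
      for (try in 1:10) {
        idx <- with_seed(fan_seed(split_seed, "try", try),
                         sample.int(n, n_test))
        if (length(unique(data$pres[idx])) == 2L &&
            length(unique(data$pres[-idx])) == 2L) {
          test_idx <- idx
          break
        }
      }
      if (is.null(test_idx))
        stop("could not draw a split with both classes on both sides")
      fit <- fit_sdm(family, data[-test_idx, ], seed = split_seed)
      train_scores <- predict(fit, data[-test_idx, ])
      test_scores <- predict(fit, data[test_idx, ])
      test_labels <- data$pres[test_idx]
      cuts <- vapply(threshold_methods(), function(m)
        find_cutoff(train_scores, data$pres[-test_idx], m)$cutoff, 0)
      cm <- confusion_at(test_scores, test_labels, cuts[["max_sens_spec"]])
      k <- k + 1L
      out[[k]] <- data.frame(
        family = family, pa_set = s, rep = r,
        auc = auc(test_scores, test_labels),
        tss = tss(cm["tp"], cm["fn"], cm["tn"], cm["fp"]),
        cutoff_equal_sens_spec = cuts[["equal_sens_spec"]],
        cutoff_max_sens_spec = cuts[["max_sens_spec"]],
        cutoff_min_roc_distance = cuts[["min_roc_distance"]],
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
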