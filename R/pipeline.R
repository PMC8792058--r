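#' Request a virtual species by elevation band
#'
#' A pipeline-resolvable species description: the niche centre is placed at
#' the median climate of the cells in the given elevation band (so the
#' ground truth is expressed in the landscape's own climate axes), with
#' breadth proportional to the landscape-wide axis spread.
#'
#' @param species_id character id.
#' @param elevation_band metres: the band whose median climate becomes the
#'   niche optimum.
#' @param n_occurrences occurrences to sample (> 30).
#' @param prevalence fraction of the landscape counted as truly suitable.
#' @param breadth_scale niche breadth as a multiple of the landscape-wide
#'   standard deviation of each axis.
#' @return object of class `species_request`.
#' @export
species_request <- function(species_id, elevation_band = c(2000, 2400),
                            n_occurrences = 150L, prevalence = 0.1,
                            breadth_scale = 0.5) {
  if (n_occurrences <= 30) stop("`n_occurrences` must exceed 30")
  structure(list(species_id = species_id, elevation_band = elevation_band,
                 n_occurrences = as.integer(n_occurrences),
                 prevalence = prevalence, breadth_scale = breadth_scale),
            class = "species_request")
}

#' Configure the end-to-end pipeline
#'
#' @param landscape a [landscape_config()].
#' @param species list of [species_request()] and/or [species_truth()]
#'   objects.
#' @param families SDM families to run (default all five).
#' @param sdm_specs named list mapping family to [sdm_spec()]; a spec with
#'   `pa_count = NA` matches the presence count at run time.  `NULL` uses
#'   [default_sdm_spec()] for every family (the full-size design).
#' @param thresholds ROC threshold methods (default all three).
#' @param gwr_bandwidth_m GWR kernel bandwidth; default 3 coarse cells.
#' @param bin_shape climate-bin grid (default 12 x 10 = 120 classes).
#' @param delta_years elapsed years for the velocity denominator.
#' @param alpha significance level of the statistics stage.
#' @param robustness_reps,robustness_scheme randomization settings used
#'   inside the pipeline run (see [randomization_robustness()]).
#' @param tci_subfactor sub-cell DEM refinement factor for TCI (default 5:
#'   a 10 m surface inside 50 m cells).
#' @param latitude_deg latitude for the irradiation proxy.
#' @param seed master seed (defaults to the landscape seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            species = list(species_request("sp1")),
                            families = sdm_families(),
                            sdm_specs = NULL,
                            thresholds = threshold_methods(),
                            gwr_bandwidth_m = NULL,
                            bin_shape = c(12L, 10L),
                            delta_years = 74,
                            alpha = 0.05,
                            robustness_reps = 200L,
                            robustness_scheme = "cap_1000",
                            tci_subfactor = 5L,
                            latitude_deg = 46,
                            seed = NULL) {
  stopifnot(inherits(landscape, "landscape_config"))
  families <- match.arg(families, sdm_families(), several.ok = TRUE)
  thresholds <- match.arg(thresholds, threshold_methods(), several.ok = TRUE)
  if (!is.null(sdm_specs)) {
    if (is.null(names(sdm_specs)) || !all(names(sdm_specs) %in% sdm_families()))
      stop("`sdm_specs` must be a named list keyed by family")
  }
  if (delta_years <= 0) stop("`delta_years` must be positive")
  structure(
    list(landscape = landscape, species = species, families = families,
         sdm_specs = sdm_specs, thresholds = thresholds,
         gwr_bandwidth_m = gwr_bandwidth_m, bin_shape = as.integer(bin_shape),
         delta_years = delta_years, alpha = alpha,
         robustness_reps = as.integer(robustness_reps),
         robustness_scheme = robustness_scheme,
         tci_subfactor = as.integer(tci_subfactor),
         latitude_deg = latitude_deg,
         seed = if (is.null(seed)) landscape$seed else as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Demonstration-scale pipeline configuration
#'
#' The small-landscape configuration used throughout the package's tests
#' and worked examples: a 200 x 200 cell 50 m grid (10 x 10 km), five GCMs,
#' two rcps, one mid-/high-elevation virtual species with 150 occurrences,
#' and reduced pseudo-absence replication (1000 x 2 sets for the regression
#' families, presence-matched x 2 sets for the tree families) so a full run
#' completes in minutes on one core.
#'
#' @param seed master seed.
#' @param extent_cells fine-grid dimensions.
#' @return a [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L, extent_cells = c(200L, 200L)) {
  ls <- landscape_config(extent_cells = extent_cells, seed = seed)
  specs <- list(
    glm = sdm_spec(1000L, pa_sets = 2L),
    gam = sdm_spec(1000L, pa_sets = 2L),
    gbm = sdm_spec(NA_integer_, pa_sets = 2L),
    rf = sdm_spec(NA_integer_, pa_sets = 2L),
    cta = sdm_spec(NA_integer_, pa_sets = 2L)
  )
  pipeline_config(
    landscape = ls,
    species = list(species_request("synthetic_endemic",
                                   elevation_band = c(2000, 2400),
                                   n_occurrences = 150L)),
    sdm_specs = specs,
    robustness_reps = 200L,
    seed = seed
  )
}

#' Species eligibility filter
#'
#' Retains species with strictly more than `min_occurrences` thinned
#' occurrences (the classical modelling floor of 30).
#'
#' @param occurrences thinned occurrence data frame with a `species`
#'   column.
#' @param min_occurrences the floor; a species needs MORE than this many.
#' @return list with `eligible` (character vector) and `skipped` (data
#'   frame of species and counts).
#' @export
check_species_eligibility <- function(occurrences, min_occurrences = 30L) {
  if (nrow(occurrences) == 0L)
    return(list(eligible = character(0),
                skipped = data.frame(species = character(0), n = integer(0))))
  n <- table(occurrences$species)
  ok <- n > min_occurrences
  list(eligible = names(n)[ok],
       skipped = data.frame(species = names(n)[!ok],
                            n = as.integer(n[!ok]), row.names = NULL))
}

resolve_truth <- function(sp, axes_baseline, dem, geology) {
  if (inherits(sp, "species_truth")) return(sp)
  stopifnot(inherits(sp, "species_request"))
  elev <- as.vector(dem$values)
  in_band <- !is.na(elev) & elev >= sp$elevation_band[1] &
    elev <= sp$elevation_band[2] & as.vector(geology$values) > 0
  p1 <- as.vector(axes_baseline$pc1$values)
  p2 <- as.vector(axes_baseline$pc2$values)
  in_band <- in_band & !is.na(p1) & !is.na(p2)
  if (!any(in_band)) stop("no carbonate cells in the requested elevation band")
  species_truth(
    sp$species_id,
    niche_center = c(median(p1[in_band]), median(p2[in_band])),
    niche_breadth = sp$breadth_scale * c(sd(p1, na.rm = TRUE), sd(p2, na.rm = TRUE)),
    n_occurrences = sp$n_occurrences,
    prevalence = sp$prevalence
  )
}

resolve_spec <- function(config, family, n_presences) {
  spec <- if (!is.null(config$sdm_specs) && !is.null(config$sdm_specs[[family]]))
    config$sdm_specs[[family]]
  else default_sdm_spec(family, n_presences)
  if (is.na(spec$pa_count)) spec$pa_count <- as.integer(n_presences)
  spec
}

extract_axes <- function(axes, x, y) {
  data.frame(pc1 = extract_values(axes$pc1, x, y),
             pc2 = extract_values(axes$pc2, x, y))
}

#' Run the full range-dynamics pipeline
#'
#' Executes, in order: synthetic landscape generation, terrain metrics,
#' pooled-PCA climate axes, GWR downscaling, virtual-species sampling and
#' thinning, the eligibility filter, the five-family SDM ensemble with
#' repeated split-sample validation, ROC binarization (3 thresholds),
#' majority consensus with geology masking, loss/stable/gain range
#' accounting (consensus headline plus per-combination mean and sd),
#' climate-change velocity per rcp, and the category-wise statistics.
#' Reruns with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: plain-text artefacts (ASCII grids,
#'   CSV tables) are written there.
#' @param verbose print stage progress messages.
#' @return a list of class `rangedyn_run`; see the package vignette for the
#'   component-by-component description.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[rangedyn] ", ...)
  ls <- config$landscape
  seed <- config$seed

  say("landscape: DEM, terrain, bioclim, geology")
  dem <- make_dem(ls)
  terr <- terrain_stack(dem, config$latitude_deg)
  sub_cfg <- ls
  sub_cfg$extent_cells <- ls$extent_cells * config$tci_subfactor
  sub_cfg$fine_cell_m <- ls$fine_cell_m / config$tci_subfactor
  tci_fine <- tci(make_dem(sub_cfg), coarse_cell_m = ls$fine_cell_m)
  dem_coarse <- block_aggregate(dem, ls$coarse_factor)
  scenarios <- make_bioclim(dem_coarse, ls)
  geology <- make_geology_mask(dem, ls$carbonate_fraction, fan_seed(seed, "geology"))

  say("climate axes: pooled PCA + GWR downscaling (", length(scenarios), " scenarios)")
  pca <- pooled_pca(scenarios)
  axes_fine <- lapply(names(scenarios), function(tag) {
    ax <- pca$per_scenario_axes[[tag]]
    list(pc1 = gwr_downscale(ax$pc1, terr, config$gwr_bandwidth_m),
         pc2 = gwr_downscale(ax$pc2, terr, config$gwr_bandwidth_m))
  })
  names(axes_fine) <- names(scenarios)
  baseline_axes <- axes_fine[["baseline"]]

  rcps <- names(ls$rcp_offsets_K)
  gcms <- sprintf("GCM%d", seq_len(ls$n_gcms))

  say("virtual species: sampling, thinning, eligibility")
  truths <- lapply(config$species, resolve_truth, axes_baseline = baseline_axes,
                   dem = dem, geology = geology)
  occ_all <- do.call(rbind, lapply(truths, make_species,
                                   pc1 = baseline_axes$pc1,
                                   pc2 = baseline_axes$pc2,
                                   geology = geology, seed = seed))
  thinned <- thin_occurrences(occ_all, dem)
  elig <- check_species_eligibility(thinned)

  species_out <- list()
  for (truth in truths) {
    sp <- truth$species_id
    if (!sp %in% elig$eligible) {
      say("species ", sp, ": skipped (too few occurrences)")
      next
    }
    say("species ", sp, ": SDM ensemble")
    pres_xy <- thinned[thinned$species == sp, ]
    pres <- extract_axes(baseline_axes, pres_xy$x, pres_xy$y)
    pres <- pres[complete.cases(pres), , drop = FALSE]
    pres$pres <- 1

    evals <- list()
    cutoffs <- list()   # cutoffs[[family]][[method]]
    suit <- list()      # suit[[family]][[tag]]
    for (family in config$families) {
      spec <- resolve_spec(config, family, nrow(pres))
      datasets <- lapply(seq_len(spec$pa_sets), function(s) {
        pas_xy <- sample_pseudo_absences(baseline_axes$pc1, pres_xy,
                                         spec$pa_count, pa_set = s,
                                         seed = fan_seed(seed, sp, family))
        pas <- extract_axes(baseline_axes, pas_xy$x, pas_xy$y)
        pas <- pas[complete.cases(pas), , drop = FALSE]
        pas$pres <- 0
        rbind(pres, pas)
      })
      cv <- cross_validate(family, datasets, spec,
                           seed = fan_seed(seed, sp, family))
      evals[[family]] <- cv
      # one cutoff per method: median over repeats within a PA set, then
      # median over PA sets
      cutoffs[[family]] <- lapply(setNames(nm = config$thresholds), function(m) {
        col <- paste0("cutoff_", m)
        per_set <- vapply(split(cv[[col]], cv$pa_set), median, 0)
        median(per_set)
      })
      fits <- lapply(seq_len(spec$pa_sets), function(s)
        fit_sdm(family, datasets[[s]],
                seed = fan_seed(seed, sp, family, "final", s)))
      suit[[family]] <- lapply(axes_fine, function(ax) {
        maps <- lapply(fits, predict_suitability, predict_stack = ax)
        acc <- Reduce(function(a, b) raster_map(`+`, a, b), maps)
        raster_map(function(x) x / length(maps), acc)
      })
    }

    say("species ", sp, ": binarization, consensus, range accounting")
    proj_baseline <- list()
    for (family in config$families)
      for (m in config$thresholds)
        proj_baseline[[paste(family, m, sep = ".")]] <-
          binarize(suit[[family]][["baseline"]], cutoffs[[family]][[m]])
    cons_baseline <- apply_geology_mask(majority_consensus(proj_baseline), geology)

    proj_future <- list()   # proj_future[[rcp]][[family.method.gcm]]
    range_out <- list()
    for (rcp in rcps) {
      proj_future[[rcp]] <- list()
      for (g in gcms) {
        tag <- paste(g, rcp, sep = "_")
        for (family in config$families)
          for (m in config$thresholds)
            proj_future[[rcp]][[paste(family, m, g, sep = ".")]] <-
              binarize(suit[[family]][[tag]], cutoffs[[family]][[m]])
      }
      cons_future <- apply_geology_mask(majority_consensus(proj_future[[rcp]]),
                                        geology)
      headline <- range_change_maps(cons_baseline, cons_future)

      combos <- list()
      for (family in config$families)
        for (m in config$thresholds)
          for (g in gcms) {
            b <- apply_geology_mask(proj_baseline[[paste(family, m, sep = ".")]],
                                    geology)
            f <- apply_geology_mask(
              proj_future[[rcp]][[paste(family, m, g, sep = ".")]], geology)
            n <- count_categories(classify_cells(b, f))
            row <- if (n[["PR"]] > 0)
              as.data.frame(range_change(n[["PR"]], n[["RL"]], n[["RG"]]))
            else data.frame(rc_pct = NA_real_, rl_pct = NA_real_,
                            rg_pct = NA_real_)
            combos[[paste(family, m, g, sep = ".")]] <-
              cbind(data.frame(algorithm = family, threshold = m, gcm = g), row)
          }
      combos <- do.call(rbind, c(combos, list(make.row.names = FALSE)))
      ok <- complete.cases(combos[c("rc_pct", "rl_pct", "rg_pct")])
      range_out[[rcp]] <- list(
        consensus_future = cons_future,
        category_map = headline$category_map,
        counts = headline$counts,
        rc_pct = headline$rc_pct, rl_pct = headline$rl_pct,
        rg_pct = headline$rg_pct,
        combinations = combos,
        summary = summarize_combinations(combos[ok, , drop = FALSE])
      )
    }

    species_out[[sp]] <- list(
      truth = truth,
      occurrences = pres_xy,
      evaluations = do.call(rbind, evals),
      cutoffs = cutoffs,
      suitability = suit,
      projections_baseline = proj_baseline,
      projections_future = proj_future,
      consensus_baseline = cons_baseline,
      range = range_out
    )
  }

  say("climate-change velocity")
  velocity <- list()
  for (rcp in rcps) {
    per_gcm <- lapply(gcms, function(g) {
      tag <- paste(g, rcp, sep = "_")
      breaks <- climate_bin_breaks(list(baseline_axes, axes_fine[[tag]]),
                                   shape = config$bin_shape)
      bb <- bin_climate(baseline_axes$pc1, baseline_axes$pc2, breaks = breaks)
      bf <- bin_climate(axes_fine[[tag]]$pc1, axes_fine[[tag]]$pc2,
                        breaks = breaks)
      dist <- nearest_analog_distance(bb, bf)
      ccv_transform(dist, config$delta_years)
    })
    velocity[[rcp]] <- average_over_gcms(per_gcm)
  }

  say("category statistics")
  covariates <- c(list(elevation = dem, tci = tci_fine, tri = terr$tri),
                  setNames(velocity, paste0("ccv_", rcps)))
  land_tab <- data.frame(lapply(covariates, function(r) as.vector(r$values)))
  land_tab <- land_tab[complete.cases(land_tab), , drop = FALSE]
  stats_out <- list(landscape_correlations = pearson_matrix(land_tab),
                    species = list())
  for (sp in names(species_out)) {
    per_rcp <- list()
    for (rcp in rcps) {
      tab <- build_cell_table(species_out[[sp]]$range[[rcp]]$category_map,
                              covariates)
      vars <- names(covariates)
      if (nlevels(droplevels(tab$category)) >= 2L) {
        kw <- lapply(setNames(nm = vars), function(v)
          kruskal_wallis(tab[[v]], tab$category))
        pw <- lapply(setNames(nm = vars), function(v)
          pairwise_mann_whitney(tab[[v]], tab$category))
        rob <- randomization_robustness(
          tab, variables = vars, scheme = config$robustness_scheme,
          reps = config$robustness_reps, alpha = config$alpha,
          seed = fan_seed(seed, "robust", sp, rcp))
      } else {
        say("species ", sp, " ", rcp,
            ": a single range-change category; category tests skipped")
        kw <- pw <- rob <- NULL
      }
      per_rcp[[rcp]] <- list(cell_table = tab, kruskal_wallis = kw,
                             pairwise = pw, robustness = rob)
    }
    stats_out$species[[sp]] <- per_rcp
  }

  run <- structure(list(
    config = config, dem = dem, dem_coarse = dem_coarse, terrain = terr,
    tci = tci_fine, geology = geology, scenarios = scenarios, pca = pca,
    axes_fine = axes_fine, occurrences = occ_all, thinned = thinned,
    eligibility = elig, species = species_out, velocity = velocity,
    stats = stats_out), class = "rangedyn_run")

  if (!is.null(out_dir)) write_run(run, out_dir, say)
  run
}

write_run <- function(run, out_dir, say = function(...) NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("writing artefacts to ", out_dir)
  write_ascii_grid(run$dem, file.path(out_dir, "dem.asc"))
  write_ascii_grid(run$geology, file.path(out_dir, "geology.asc"))
  write_ascii_grid(run$tci, file.path(out_dir, "tci.asc"))
  write_ascii_grid(run$terrain$tri, file.path(out_dir, "tri.asc"))
  for (rcp in names(run$velocity))
    write_ascii_grid(run$velocity[[rcp]],
                     file.path(out_dir, paste0("ccv_", rcp, ".asc")))
  write.csv(run$thinned, file.path(out_dir, "occurrences_thinned.csv"),
            row.names = FALSE)
  for (sp in names(run$species)) {
    s <- run$species[[sp]]
    write.csv(s$evaluations,
              file.path(out_dir, paste0(sp, "_evaluations.csv")),
              row.names = FALSE)
    write_ascii_grid(s$consensus_baseline,
                     file.path(out_dir, paste0(sp, "_consensus_baseline.asc")))
    for (rcp in names(s$range)) {
      write_ascii_grid(s$range[[rcp]]$category_map,
                       file.path(out_dir, paste0(sp, "_categories_", rcp, ".asc")))
      write.csv(s$range[[rcp]]$combinations,
                file.path(out_dir, paste0(sp, "_combinations_", rcp, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.rangedyn_run <- function(x, ...) {
  cat("<rangedyn_run>\n")
  cat(sprintf("  landscape: %d x %d cells @ %g m (coarse factor %d)\n",
              x$config$landscape$extent_cells[1], x$config$landscape$extent_cells[2],
              x$config$landscape$fine_cell_m, x$config$landscape$coarse_factor))
  cat(sprintf("  scenarios: %d (baseline + %d GCM x %d rcp)\n",
              length(x$scenarios), x$config$landscape$n_gcms,
              length(x$config$landscape$rcp_offsets_K)))
  for (sp in names(x$species)) {
    cat(sprintf("  species %s:\n", sp))
    for (rcp in names(x$species[[sp]]$range)) {
      r <- x$species[[sp]]$range[[rcp]]
      cat(sprintf("    %s: RC %.1f%%, RL %.1f%%, RG %.1f%% (consensus)\n",
                  rcp, r$rc_pct, r$rl_pct, r$rg_pct))
    }
  }
  invisible(x)
}
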