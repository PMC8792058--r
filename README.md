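# rangedyn

Fine-scale range dynamics of narrow endemic mountain plants under climate
change: an end-to-end, fully reproducible pipeline in R.

Narrow endemics of carbonate mountain ranges live in small climatic
envelopes on particular bedrock. Projecting their fate under warming with
~1 km climate grids misses the microclimate that decides local
persistence, so this package statistically downscales climate to a 50 m
grid and runs the whole analysis chain at that resolution:

* **Climate axes** — one principal-component analysis of the 19
  bioclimatic variables with baseline and all future scenarios pooled,
  yielding two shared axes (PC1, PC2).
* **Topographic downscaling** — geographically weighted regression of each
  coarse axis on elevation, slope, northness `cos(aspect)`, eastness
  `sin(aspect)` and an irradiation proxy, predicted at 50 m.
* **Ensemble SDMs** — five families (GLM, GAM, GBM, RF, CTA) on
  presence/pseudo-absence data, evaluated by 10 repeated 70/30
  split-sample validations with AUC and TSS = sensitivity + specificity − 1.
* **Binarization and consensus** — three ROC threshold rules (equal
  sensitivity/specificity, max sensitivity + specificity, minimum distance
  to the ROC corner); with 5 algorithms, 5 GCMs and 2 rcp scenarios this
  gives 15 baseline and 165 total binary projections per species, combined
  by a ≥ 50% majority vote and masked to carbonate geology.
* **Range accounting** — per-cell loss/stable/gain categories and
  `RC = 100 · (RG − RL) / PR`, where PR is the number of baseline-suitable
  cells; `RL%` is the no-dispersal readout and `RC%` the full-dispersal
  readout, summarised as mean ± sd across all algorithm × threshold × GCM
  combinations.
* **Terrain heterogeneity** — TRI (mean |elevation difference| to the 8
  neighbours) and TCI (within-cell 3D/2D surface-area ratio,
  `Σ A_fine / cos(slope_fine) / A_coarse ≥ 1`).
* **Climate-change velocity** — 120 unique-climate bins on (PC1, PC2);
  per cell, the distance to the nearest future analog of its baseline
  climate divided by the elapsed years; `CCV = 100 · log10(m yr⁻¹)`,
  averaged over GCMs. The nearest-analog search uses an exact Euclidean
  distance transform and matches a brute-force oracle exactly.
* **Category statistics** — Pearson correlations among the landscape
  covariates, Kruskal–Wallis and pairwise Mann–Whitney (Bonferroni) tests
  of elevation/TRI/TCI/CCV among loss, stable and gain cells, plus a
  1000-replicate randomization robustness procedure.

A first-class synthetic-landscape generator (plateau massifs with summit
cones, 19 correlated bioclim layers, carbonate mask, virtual species with
a known Gaussian niche) makes every stage testable against ground truth
with no downloads. See the methods vignette
(`vignettes/range-dynamics-methods.Rmd`) for models, conventions and
defaults.

## Worked example

```r
library(rangedyn)
run <- run_pipeline(demo_pipeline_config(seed = 1))
print(run)
#> <rangedyn_run>
#>   landscape: 200 x 200 cells @ 50 m (coarse factor 20)
#>   scenarios: 11 (baseline + 5 GCM x 2 rcp)
#>   species synthetic_endemic:
#>     rcp45: RC -56.8%, RL 75.3%, RG 18.5% (consensus)
#>     rcp85: RC -94.5%, RL 100.0%, RG 5.5% (consensus)
```

The demonstration run (under a minute on one core) builds a 10 × 10 km
synthetic landscape, samples 150 occurrences of a virtual species whose
niche is centred on the 2000–2400 m climate, and pushes them through the
full chain. Under the intermediate scenario the consensus range loses
75.3% of its baseline cells and gains 18.5% elsewhere, a net range change
of −56.8%; under the severe scenario the modelled range collapses
(RL = 100%). Held-out discrimination per family:

```r
round(tapply(run$species[[1]]$evaluations$auc,
             run$species[[1]]$evaluations$family, mean), 3)
#>   cta   gam   gbm   glm    rf
#> 0.834 0.886 0.854 0.906 0.845
```

Loss sits below stability on the mountain, and the flat highlands see
faster climate displacement than the steep mid-slopes:

```r
tab <- run$stats$species[[1]]$rcp45$cell_table
round(tapply(tab$elevation, tab$category, median))
#>   loss stable   gain
#>   2157   2300     NA
```

(The gain cells of this run all lie where the severe-scenario CCV is
undefined, so they drop out of the covariate table.) The per-combination
summary corresponding to the consensus numbers above is
`run$species[[1]]$range$rcp45$summary` (mean RC −55.5%, sd 6.9% across the
75 algorithm × threshold × GCM combinations).

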