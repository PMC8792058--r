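---
title: "Methods: fine-scale range dynamics of narrow endemic mountain plants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale range dynamics of narrow endemic mountain plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangedyn)
```

# The problem

Narrow endemic mountain plants occupy small ranges pinned to particular
bedrock and a thin climatic envelope.  Coarse (~1 km) climate grids smooth
away exactly the microclimatic variation — cold air pooling below cliffs,
contrasts between north and south faces, high flat plateaus — that decides
whether such a species can persist locally under warming.  `rangedyn`
implements a complete, reproducible pipeline for projecting fine-scale
(50 m) range dynamics under climate-change scenarios and for asking *where*
the projected losses, gains and stable areas sit with respect to elevation,
terrain heterogeneity and the velocity of climate change.

The pipeline has eight stages, each exposed as ordinary functions and wired
together by `run_pipeline()`:

1. **Synthetic landscape** (`make_dem()`, `make_bioclim()`,
   `make_geology_mask()`, `make_species()`, `thin_occurrences()`): a
   virtual study area with known ground truth.
2. **Terrain metrics** (`slope_aspect()`, `northness_eastness()`,
   `dni_proxy()`, `tri()`, `tci()`, `resample_nearest()`).
3. **Climate axes** (`pooled_pca()`): the 19 bioclimatic variables of all
   scenarios, baseline and future pooled together, are standardised and
   decomposed once; the first two components are the climate predictors
   everywhere downstream.
4. **Downscaling** (`gwr_downscale()`): geographically weighted regression
   of each coarse axis on five topographic predictors (elevation, slope,
   northness, eastness, irradiation), predicted onto the 50 m grid.
5. **SDM ensemble** (`fit_sdm()`, `cross_validate()`): five algorithm
   families — logistic regression with quadratic terms (GLM), additive
   logistic smooths (GAM), boosted trees (GBM), random forest (RF) and a
   single classification tree (CTA) — fitted to presences plus
   pseudo-absences on the two axes, evaluated by 10 repeated 70/30
   split-sample validations with AUC and TSS.
6. **Binarization and consensus** (`find_cutoff()`, `binarize()`,
   `majority_consensus()`, `apply_geology_mask()`): three ROC threshold
   rules convert each continuous map into binary projections — with five
   algorithms, five GCMs and two rcp scenarios this yields 15 baseline and
   165 total projections per species — then a >= 50% majority vote and a
   carbonate-geology mask produce one consensus range per climate.
7. **Range accounting** (`classify_cells()`, `range_change()`,
   `summarize_combinations()`): per-cell loss/stable/gain/unsuitable
   categories and the range-change readouts
   `RC = 100 (RG - RL) / PR`, with `RL%` read as the no-dispersal scenario
   and `RC%` as the full-dispersal scenario; means and standard deviations
   are reported across all algorithm x threshold x GCM combinations.
8. **Velocity and statistics** (`bin_climate()`,
   `nearest_analog_distance()`, `ccv_transform()`, `average_over_gcms()`;
   `pearson_matrix()`, `kruskal_wallis()`, `pairwise_mann_whitney()`,
   `randomization_robustness()`).

# The synthetic landscape

Every stage is exercised end-to-end on a generated landscape whose
statistical structure matches the assumptions of the analysis, so that
parameter recovery can be tested against known truth without downloading
any real raster.

**Topography.** The DEM is a sum of logistic "shoulders" around massif
centres (flat valley floors, steep mid-elevation walls, flat highlands),
plus small Gaussian summit cones rising above the highland level, a gentle
regional tilt and smoothed noise.  The geomorphic scales are metric
(about 3 km highland radius, 450 m shoulder width, 600 m summit cones)
because mountain shape does not scale with the study extent.  Two features
are deliberate:

* the median slope is maximal in the *middle* elevation band — the
  hypsometry that drives the velocity result below; and
* the summit cones leave climatic headroom above the highlands, so the
  highland climates do not simply vanish under moderate warming but
  retreat to small distant summits.

**Climate.** Nineteen bioclimatic layers are generated on the coarse grid
(default one coarse cell = 20 x 20 fine cells, i.e. ~1 km over a 50 m
grid): seven temperature-like layers decreasing with elevation at a lapse
rate of 6.5 K/km (the standard free-air value), four
temperature/precipitation mixtures, and eight precipitation-like layers
with an orographic elevation term plus a shared east-west
moisture-advection gradient that is independent of elevation.  The
moisture gradient matters: without a second *spatially structured* climate
dimension, the second principal component would be dominated by the
temporal warming signal and no cell would have a future climate analog
anywhere — an artefact of over-simplified synthetic climates, not a
property of real bioclim grids.

**Scenarios.** Future layers are the baseline plus a per-rcp warming
offset applied in proportion to each layer's temperature content (+2.5 K
for rcp 4.5 and +4.5 K for rcp 8.5, the deltas a practitioner would quote
for the Alps between a 1979-2013 baseline and a 2061-2080 horizon), plus a
smooth per-GCM perturbation field (sd 0.15 K by default) emulating five
circulation models.  Setting all offsets and the jitter to zero reproduces
the baseline bit-for-bit, which the tests exploit.

**Geology and species.** The carbonate mask is a smoothed Gaussian field
thresholded at the requested areal fraction (default 0.7).  A virtual
species is a Gaussian niche in (PC1, PC2) space restricted to carbonate;
occurrences are cells sampled without replacement with probability
proportional to suitability, then thinned to one per 50 m cell (keeping
the first point in input order — a deterministic rule, since the original
protocol does not specify which point survives thinning).  Species enter
the modelling stage only with strictly more than 30 thinned occurrences.

**What the generator does not emulate** — and hence what passing tests do
and do not show: real meteorology (no seasonality, no interannual
variability), dispersal limitation, biotic interactions, observation bias
in occurrences, and the bounded, irregular outline of a real study region.
Recovery results on this landscape demonstrate that the machinery is
correct and well-calibrated, not that any particular real species is
projected accurately.

# Models and conventions

**Pooled PCA.** The 19 variables are centred and scaled on the pooled
(all scenarios) sample before decomposition, since their units are
heterogeneous.  Axis signs are fixed deterministically: PC1 is oriented to
correlate positively with the mean of the temperature-like layers, PC2 so
that its largest-magnitude loading is positive.  Constant layers are
dropped with a warning.

**GWR downscaling.** At each coarse cell a weighted least-squares fit of
the axis on the five block-averaged topographic predictors uses a Gaussian
kernel over coarse-cell centre distances; the default bandwidth is three
coarse cell widths (the protocol this follows does not publish a
bandwidth, so it is a configurable default chosen to keep roughly a
neighbourhood of ~30 cells effective).  Predictors are standardised by
their coarse moments for conditioning.  Fine cells inherit their parent
coarse cell's coefficients.  A rank-deficient local design (e.g. flat
terrain) falls back to the kernel-weighted local mean with a warning, so
constant terrain degrades gracefully to kernel smoothing of the coarse
field.  A planted linear signal `a*elevation + b` is recovered on the fine
grid essentially exactly, and block-averaging a downscaled field back to
the coarse grid reproduces the coarse axis within a few percent of its
range (mass consistency).

**Terrain.** Slope and aspect use Horn's 8-neighbour method (the classical
`terrain()` default); aspect is the *downslope* (facing) direction,
clockwise from north, with flat cells assigned aspect 0 and flagged.
Border cells are nodata for slope/aspect; TRI instead uses the available
3, 5 or 8 neighbours so it stays defined at the grid edge.  TCI is the
within-coarse-cell ratio of slope-corrected 3-D area to planimetric area,
`mean(1 / cos(slope_fine))`, computed from a finer DEM (the pipeline
refines the landscape five-fold, i.e. 10 m inside 50 m cells); flat
terrain gives exactly 1 and a uniform 45 degree plane exactly sqrt(2).
The irradiation layer is a deterministic clear-sky proxy (equinox-noon
beam incidence at the configured latitude) standing in for a downloaded
irradiation product; it preserves the property the downscaling needs —
south-facing slopes receive more energy than north-facing ones.

**Thresholds and consensus.** Cutoff candidates are the distinct observed
scores plus 0 and 1; among equally optimal candidates the smallest is
returned, and a suitability exactly at the cutoff counts as presence.
Cutoffs are computed on training scores, per cross-validation repeat, then
collapsed to one cutoff per family and rule by taking medians (first
across the 10 repeats within a pseudo-absence set, then across sets) —
necessary because one binary projection per algorithm x threshold (x GCM)
is produced, not one per repeat.  The majority vote pools all projections
of a given climate and counts an exact 50% tie as presence.  The geology
mask is applied after the vote; since the mask is idempotent and cellwise,
the order does not change the result.

**Pseudo-absences.** The full-size design follows the common
recommendation: 10000 background points in 3 sets for the regression
families, presence-matched counts in 10 sets for the tree-based families,
equal class weights within a fit.  The demonstration configuration scales
this to 1000 x 2 sets (regression) and presence-matched x 2 sets (trees)
— on a 40 000-cell landscape, 10 000 background points would be a quarter
of all cells, which distorts rather than represents the background.

**Climate velocity.** The two fine-grid axes are discretised into 120
unique-climate bins (12 x 10 over the pooled baseline + future ranges; the
source protocol fixes only the total).  For each cell, the velocity is the
distance to the nearest cell whose *future* climate falls in the cell's
*baseline* bin, divided by the elapsed years — 74 by default (midpoint
1996 of 1979-2013 to midpoint 2070 of 2061-2080; the commonly quoted
round value 75 is accepted via configuration).  Zero distances are floored
at half a cell width so the log scale stays finite; classes absent from
the future map are flagged no-analog and excluded rather than given a
number.  CCV is `100 * log10(velocity in m/yr)`, averaged across GCMs on
this log scale, with a cell flagged only if every GCM lacks an analog.
The nearest-analog search runs one exact Euclidean distance transform
(Felzenszwalb-Huttenlocher, in C++) per climate class, and is tested to
agree exactly with an all-pairs brute-force oracle.

**Category statistics.** Loss/stable/gain cells (never the unsuitable
background) are compared on elevation, TRI, TCI and the two CCV surfaces:
Kruskal-Wallis with the chi-square approximation (tie-corrected), pairwise
two-sided Mann-Whitney tests with Bonferroni correction, and a
randomization procedure that re-runs the Kruskal-Wallis test on 1000
without-replacement subsamples (10% of each category, 1% of each category,
or each category capped at 1000 cells) and counts significant replicates.
Cells with an undefined covariate (chiefly no-analog CCV) are excluded
from these tables.  An all-tie sample is reported as H = 0, p = 1 rather
than NaN.

# Reproducibility and problem sizes

All randomness flows from one master seed through named sub-streams
(`fan_seed()`), so every artefact — pseudo-absence sets, cross-validation
splits, stochastic learners, randomization replicates — is a pure function
of the configuration.  Two runs with the same configuration are
bit-identical, which the test suite asserts.

The demonstration configuration (`demo_pipeline_config()`) used by the
examples, the test suite and `scripts/acceptance.R` is a 200 x 200 cell
50 m landscape (10 x 10 km) with two massifs, five GCMs, two rcps, one
virtual species with 150 occurrences centred on the 2000-2400 m climate,
and the reduced pseudo-absence design above; a full run takes under a
minute on one core.  These sizes are the package's demonstration choice;
every one of them is a constructor argument.

```{r demo, eval = FALSE}
run <- run_pipeline(demo_pipeline_config(seed = 1), verbose = TRUE)
print(run)
```

# Known limitations

* The raster container is deliberately minimal (matrix + origin + square
  cell + nodata) with plain-text ASCII-grid I/O; there is no projection
  handling, and coordinates are assumed planar metric throughout.
* Binary projections inherit all the caveats of thresholding: results are
  meant for area-level trends, not single-cell claims.
* The velocity measure is forward-looking only (where does my climate go),
  uses equal-width bins, and treats disappearing climates as no-analog
  rather than assigning them a censored velocity.
* The randomization procedure addresses pseudo-replication by subsampling;
  it is not a spatially explicit autocorrelation correction.
* On a 10 x 10 km landscape some baseline climates genuinely have no
  future analog (summit tops under either scenario, and most of the
  highlands under rcp 8.5); statistics that need CCV silently lose those
  cells, and with severe warming a species can lose its entire consensus
  range, in which case the category tests are skipped for that scenario.
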