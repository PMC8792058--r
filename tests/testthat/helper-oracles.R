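# Independent brute-force oracles and shared fixtures for the test suite.
# Every oracle is a deliberately naive double-loop / enumeration version of
# the operation it checks, written against the definitions only.

rg <- function(m, cell = 1, xmin = 0) {
  raster_grid(m, xmin = xmin, ymax = nrow(m) * cell, cell = cell)
}

# TRI: mean absolute difference to available 8-neighbours, double loop.
tri_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j])) next
    diffs <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(m[ii, jj]))
        diffs <- c(diffs, abs(m[i, j] - m[ii, jj]))
    }
    out[i, j] <- mean(diffs)
  }
  out
}

# Nearest-analog distance: all-pairs scan per cell.
nad_oracle <- function(b, f, cell = 1) {
  nr <- nrow(b); nc <- ncol(b)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cl <- b[i, j]
    if (is.na(cl)) next
    best <- Inf
    for (ii in seq_len(nr)) for (jj in seq_len(nc)) {
      if (!is.na(f[ii, jj]) && f[ii, jj] == cl)
        best <- min(best, sqrt((ii - i)^2 + (jj - j)^2))
    }
    if (is.finite(best)) out[i, j] <- best * cell
  }
  out
}

# AUC as the fraction of concordant positive-negative pairs (ties = 1/2).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Majority vote per cell, explicit loop over layers.
consensus_oracle <- function(mats) {
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    votes <- vapply(mats, function(m) m[i, j], 0)
    votes <- votes[!is.na(votes)]
    if (length(votes)) out[i, j] <- as.numeric(mean(votes) >= 0.5)
  }
  out
}

# Max-TSS cutoff by exhaustive search over candidates (smallest optimum).
cutoff_tss_oracle <- function(scores, labels) {
  cand <- sort(unique(c(0, scores, 1)))
  best <- -Inf; best_cut <- NA_real_
  for (ct in cand) {
    tp <- sum(scores >= ct & labels == 1); fn <- sum(scores < ct & labels == 1)
    tn <- sum(scores < ct & labels == 0); fp <- sum(scores >= ct & labels == 0)
    val <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (val > best + 1e-12) { best <- val; best_cut <- ct }
  }
  best_cut
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_exact_oracle <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_idx <- utils::combn(length(ranks), n1)
  u_all <- apply(all_idx, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Smooth random surface (uses the caller's RNG state).
smooth_field_fixture <- function(n) {
  g <- seq(0, 2 * pi, length.out = n)
  outer(sin(g), cos(g)) * 10 + matrix(rnorm(n * n, sd = 0.3), n, n)
}

# One shared demonstration-scale pipeline run (about half a minute), reused
# by the acceptance checks that exercise the end-to-end system.
.demo_cache <- new.env(parent = emptyenv())
demo_run_cached <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (is.null(.demo_cache[[key]]))
    .demo_cache[[key]] <- run_pipeline(demo_pipeline_config(seed = seed))
  .demo_cache[[key]]
}

# Small, fast landscape for unit-level pipeline tests.
tiny_config <- function(seed = 11L) {
  ls <- landscape_config(extent_cells = c(80L, 80L), coarse_factor = 10L,
                         n_gcms = 2L, rcp_offsets_K = c(rcp45 = 2.5),
                         seed = seed)
  pipeline_config(
    landscape = ls,
    species = list(species_request("tiny_sp", elevation_band = c(1900, 2300),
                                   n_occurrences = 80L)),
    families = c("glm", "cta"),
    sdm_specs = list(glm = sdm_spec(200L, pa_sets = 1L, cv_repeats = 3L),
                     cta = sdm_spec(NA_integer_, pa_sets = 1L, cv_repeats = 3L)),
    robustness_reps = 20L,
    seed = seed
  )
}
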