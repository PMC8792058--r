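logistic_data <- function(n, seed, beta = 2) {
  with_seed(seed, {
    d <- data.frame(pc1 = rnorm(n), pc2 = rnorm(n))
    d$pres <- rbinom(n, 1, plogis(beta * d$pc1))
    d
  })
}

test_that("pseudo-absence sampling excludes presences and is reproducible", {
  dom <- rg(matrix(0, 20, 20), cell = 50)
  pres <- data.frame(x = c(25, 75, 125), y = c(25, 25, 25))
  pa <- sample_pseudo_absences(dom, pres, 100, pa_set = 1, seed = 4)
  expect_equal(nrow(pa), 100L)
  idx_pa <- cell_of(dom, pa$x, pa$y)
  idx_pr <- cell_of(dom, pres$x, pres$y)
  expect_length(intersect(paste(idx_pa$row, idx_pa$col),
                          paste(idx_pr$row, idx_pr$col)), 0L)
  expect_identical(pa, sample_pseudo_absences(dom, pres, 100, 1, seed = 4))
  expect_false(identical(pa, sample_pseudo_absences(dom, pres, 100, 2, seed = 4)))
  expect_error(sample_pseudo_absences(dom, pres, 398, 1, 4), "fewer")
})

test_that("every family separates a PC1-separable niche", {
  train <- with_seed(31, data.frame(pc1 = c(runif(80, 0.5, 2), runif(80, -2, -0.5)),
                                    pc2 = rnorm(160),
                                    pres = rep(c(1, 0), each = 80)))
  d <- 20
  stack <- list(pc1 = rg(matrix(seq(-2, 2, length.out = d * d), d), cell = 50),
                pc2 = rg(matrix(0, d, d), cell = 50))
  for (family in sdm_families()) {
    suit <- fit_predict(family, train, stack, seed = 1)
    v <- as.vector(suit$values)
    hi <- as.vector(stack$pc1$values) > 0
    expect_gt(mean(v[hi]), mean(v[!hi]))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("constant predictors give the training prevalence for the GLM", {
  train <- data.frame(pc1 = rep(1, 50), pc2 = rep(2, 50),
                      pres = rep(c(1, 0), times = c(15, 35)))
  stack <- list(pc1 = rg(matrix(1, 4, 4)), pc2 = rg(matrix(2, 4, 4)))
  suit <- fit_predict("glm", train, stack, seed = 1)
  expect_equal(unique(round(as.vector(suit$values), 8)), 15 / 50)
})

test_that("single-class training data is rejected", {
  train <- data.frame(pc1 = rnorm(10), pc2 = rnorm(10), pres = 1)
  expect_error(fit_sdm("glm", train), "both classes")
})

test_that("cross-validation yields repeats x sets held-out records", {
  d <- logistic_data(200, seed = 32)
  spec <- sdm_spec(100, pa_sets = 2, cv_repeats = 10)
  cv <- cross_validate("glm", list(d, d), spec, seed = 6)
  expect_equal(nrow(cv), 20L)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  expect_true(all(cv$tss >= -1 & cv$tss <= 1))
  expect_identical(cv, cross_validate("glm", list(d, d), spec, seed = 6))
})

test_that("cross-validated AUC is near 1 for a deterministic signal and near 0.5 under a shuffled null", {
  d <- with_seed(33, data.frame(pc1 = rnorm(300), pc2 = rnorm(300)))
  d$pres <- as.numeric(d$pc1 > 0)
  spec <- sdm_spec(150, pa_sets = 1, cv_repeats = 10)
  cv <- cross_validate("glm", d, spec, seed = 7)
  expect_gt(mean(cv$auc), 0.95)

  d$pres <- with_seed(34, sample(d$pres))
  cv0 <- cross_validate("glm", d, spec, seed = 7)
  expect_gte(mean(cv0$auc), 0.4)
  expect_lte(mean(cv0$auc), 0.6)
})

test_that("AUC equals pairwise concordance, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(55)
  for (i in 1:120) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("TSS is sensitivity plus specificity minus one", {
  expect_equal(tss(10, 0, 10, 0), 1)
  expect_equal(tss(40, 10, 30, 20), 0.4)
  expect_equal(tss(5, 5, 5, 5), 0)
  expect_error(tss(0, 0, 10, 2), "both observed classes")
})

test_that("the recommended pseudo-absence designs follow family class", {
  expect_equal(default_sdm_spec("glm", 120)$pa_count, 10000L)
  expect_equal(default_sdm_spec("glm", 120)$pa_sets, 3L)
  expect_equal(default_sdm_spec("rf", 120)$pa_count, 120L)
  expect_equal(default_sdm_spec("rf", 120)$pa_sets, 10L)
})
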