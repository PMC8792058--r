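category_fixture <- function(n = 60, shift = c(0, 0, 0), seed = 41) {
  with_seed(seed, data.frame(
    category = factor(rep(c("loss", "stable", "gain"), each = n),
                      levels = c("loss", "stable", "gain")),
    elevation = rnorm(3 * n, mean = rep(2000 + shift, each = n), sd = 50)
  ))
}

test_that("the Pearson matrix is symmetric with a unit diagonal", {
  with_seed(42, {
    tab <- data.frame(a = rnorm(50), b = rnorm(50))
    tab$c <- 2 * tab$a + 3
    m <- pearson_matrix(tab)
    expect_equal(diag(m), c(a = 1, b = 1, c = 1))
    expect_equal(m, t(m))
    expect_equal(m["a", "c"], 1)
    tab$d <- 5
    expect_warning(m2 <- pearson_matrix(tab), "constant")
    expect_true(is.na(m2["a", "d"]))
  })
})

test_that("Kruskal-Wallis separates shifted groups and not constant ones", {
  same <- category_fixture()
  same$elevation <- 7
  expect_equal(kruskal_wallis(same$elevation, same$category)$H, 0)

  far <- category_fixture(shift = c(0, 500, 1000))
  kw <- kruskal_wallis(far$elevation, far$category)
  expect_lt(kw$p_value, 0.001)
  expect_equal(kw$df, 2)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("two-group Kruskal-Wallis matches the normal-approximation rank-sum test", {
  # with two groups H is the square of the MW normal deviate (no continuity
  # correction), so the chi-square p equals the two-sided rank-sum p
  with_seed(43, {
    for (i in 1:10) {
      x <- rnorm(12)
      y <- rnorm(15, mean = runif(1, -1, 1))
      kw <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(12, 15)))
      mw <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
      expect_equal(kw$p_value, mw$p.value, tolerance = 1e-10)
    }
  })
})

test_that("pairwise rank-sum p values agree with exact enumeration for small groups", {
  with_seed(44, {
    for (i in 1:8) {
      x <- round(rnorm(6), 2); y <- round(rnorm(7, 0.5), 2)
      vals <- c(x, y); grp <- rep(c("g1", "g2"), c(6, 7))
      p <- pairwise_mann_whitney(vals, grp, correction = "none")["g2", "g1"]
      if (!anyDuplicated(vals))   # enumeration oracle assumes no ties
        expect_equal(p, mw_exact_oracle(x, y), tolerance = 1e-10)
    }
  })
})

test_that("Bonferroni adjustment multiplies and caps pairwise p values", {
  tab <- category_fixture(shift = c(0, 30, 60))
  raw <- pairwise_mann_whitney(tab$elevation, tab$category, correction = "none")
  adj <- pairwise_mann_whitney(tab$elevation, tab$category)
  k <- sum(!is.na(raw))
  expect_equal(adj[!is.na(adj)], pmin(1, k * raw[!is.na(raw)]))
  expect_true(all(adj >= raw, na.rm = TRUE))

  same <- category_fixture()
  same$elevation <- rep(c(1, 2, 3), 60)
  p_same <- pairwise_mann_whitney(same$elevation, same$category)
  expect_true(all(p_same == 1, na.rm = TRUE))
})

test_that("randomization robustness detects a planted separation every time", {
  tab <- category_fixture(n = 200, shift = c(0, 800, 1600))
  rep_ <- randomization_robustness(tab, variables = "elevation",
                                   scheme = "frac_10", reps = 100, seed = 2)
  expect_equal(rep_$counts$n_significant, 100L)
})

test_that("randomization robustness is calibrated under the null", {
  tab <- category_fixture(n = 500)
  rep_ <- randomization_robustness(tab, variables = "elevation",
                                   scheme = "frac_10", reps = 400, seed = 3)
  rate <- rep_$counts$n_significant / 400
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
  expect_identical(
    rep_$counts,
    randomization_robustness(tab, variables = "elevation", scheme = "frac_10",
                             reps = 400, seed = 3)$counts)
})

test_that("the capped scheme limits each category to 1000 cells", {
  tab <- category_fixture(n = 1500, shift = c(0, 100, 200))
  rep_ <- randomization_robustness(tab, variables = "elevation",
                                   scheme = "cap_1000", reps = 5, seed = 4)
  expect_equal(rep_$counts$reps, 5L)
  small <- category_fixture(n = 20)
  expect_warning(
    randomization_robustness(small, variables = "elevation",
                             scheme = "frac_1", reps = 2, seed = 5),
    "too small")
})

test_that("cell tables keep only loss/stable/gain rows with covariates", {
  cm <- rg(matrix(c(0, 1, 2, 3, 1, NA), 2, 3))
  cov <- list(elevation = rg(matrix(1:6 * 100, 2, 3)),
              tri = rg(matrix(c(1, 2, 3, 4, NA, 6), 2, 3)))
  tab <- build_cell_table(cm, cov)
  expect_equal(nrow(tab), 3L)  # drops unsuitable, NA category, NA covariate
  expect_setequal(levels(tab$category), c("loss", "stable", "gain"))
  expect_true(all(complete.cases(tab)))
})
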