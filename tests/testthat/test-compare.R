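test_that("chi-square on printed baseline counts reproduces the published p-values", {
  # male: 19/40 HC vs 61/120 CSVD -> p = 0.7150 at 4 decimals
  sex <- rep(c(1, 0, 1, 0), c(19, 21, 61, 59))
  grp <- rep(c("HC", "CSVD"), c(40, 120))
  res <- group_compare(sex, grp, type = "categorical")
  expect_equal(round(res$p_value, 4), 0.7150)
  # independent 2x2 arithmetic: chi2 = n(ad-bc)^2 / row/col products
  chi2_oracle <- 160 * (19 * 59 - 21 * 61)^2 / (40 * 120 * 80 * 80)
  expect_equal(res$statistic, chi2_oracle, tolerance = 1e-12)

  # hypertension: 14/40 vs 78/120 -> chi2 ~ 11.05, p < 0.001
  htn <- rep(c(1, 0, 1, 0), c(14, 26, 78, 42))
  res2 <- group_compare(htn, grp, type = "categorical")
  expect_equal(res2$statistic, 11.0486, tolerance = 1e-4)
  expect_lt(res2$p_value, 0.001)
})

test_that("identical groups give a null ANOVA and unit pairwise p", {
  v <- rep(c(12, 15, 18, 21, 24, 27, 30, 33), 3)
  g <- rep(c("HC", "CSVD-NCI", "CSVD-MCI"), each = 8)
  res <- group_compare(v, g)
  expect_equal(res$test, "anova")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_true(all(res$pairwise[[1]]$p_bonferroni == 1))
})

test_that("the normality branch picks Kruskal-Wallis for skewed data", {
  set.seed(10)
  v <- c(stats::rlnorm(40, 0, 1), stats::rlnorm(40, 0.8, 1))
  g <- rep(c("a", "b"), each = 40)
  res <- group_compare(v, g)
  expect_equal(res$test, "kruskal-wallis")
  expect_lte(res$normality_p, 0.05)

  vn <- c(stats::rnorm(40), stats::rnorm(40, 0.5))
  resn <- group_compare(vn, rep(c("a", "b"), each = 40))
  expect_equal(resn$test, "anova")
})

test_that("Bonferroni correction multiplies and caps pairwise p-values", {
  set.seed(11)
  v <- c(stats::rnorm(15, 0), stats::rnorm(15, 1.5), stats::rnorm(15, 3))
  g <- rep(c("g1", "g2", "g3"), each = 15)
  res <- group_compare(v, g)
  pw <- res$pairwise[[1]]
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_bonferroni, pmin(pw$p_raw * 3, 1))
})

test_that("degenerate categorical input is rejected", {
  expect_error(group_compare(rep(1, 20), rep(c("a", "b"), 10),
                             type = "categorical"),
               "degenerate")
  expect_error(group_compare(1:5, rep("a", 5)), "two groups")
})

test_that("compare_baseline summarises a cohort variable-by-variable", {
  tab <- make_cohort(cohort_spec(seed = 2))
  res <- compare_baseline(tab, c("age", "sex", "alps_index"),
                          categorical = "sex")
  expect_equal(res$variable, c("age", "sex", "alps_index"))
  expect_equal(res$test[2], "chi-square")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
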