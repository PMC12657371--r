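test_that("near-deterministic linear structure is decomposed exactly", {
  n <- 50
  x <- seq(-2, 2, length.out = n)
  set.seed(1)
  m <- 0.5 * x + rnorm(n, sd = 1e-6)      # infinitesimal mediator noise keeps
  d <- data.frame(x = x, m = m,           # the design identifiable
                  y = 0.3 * x + 0.4 * m)
  fit <- suppressWarnings(mediate(d, "x", "m", "y", n_boot = 100, seed = 1))
  est <- setNames(fit$paths$estimate, fit$paths$path)
  expect_equal(est[["a"]], 0.5, tolerance = 1e-4)
  expect_equal(est[["b"]], 0.4, tolerance = 1e-4)
  expect_equal(est[["c_prime"]], 0.3, tolerance = 1e-4)
  expect_equal(est[["c"]], 0.5, tolerance = 1e-4)
  expect_equal(fit$indirect, 0.2, tolerance = 1e-4)
  expect_equal(fit$mediation_percent, 40, tolerance = 1e-3)
})

test_that("the OLS identity c = c_prime + a*b holds exactly with covariates", {
  set.seed(40)
  for (i in 1:8) {
    n <- 60 + i * 10
    d <- data.frame(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
    d$m <- 0.4 * d$x + 0.3 * d$c1 + rnorm(n)
    d$y <- 0.2 * d$x + 0.5 * d$m - 0.2 * d$c2 + rnorm(n)
    fit <- mediate(d, "x", "m", "y", c("c1", "c2"), n_boot = 20, seed = i)
    est <- setNames(fit$paths$estimate, fit$paths$path)
    expect_lt(abs(est[["c"]] - (est[["c_prime"]] + fit$indirect)), 1e-10)
  }
})

test_that("the bootstrap is reproducible and the CI brackets the estimate", {
  set.seed(41)
  d <- data.frame(x = rnorm(150))
  d$m <- -0.5 * d$x + rnorm(150, sd = 0.5)
  d$y <- 4 * d$m - d$x + rnorm(150)
  f1 <- mediate(d, "x", "m", "y", n_boot = 400, seed = 99)
  f2 <- mediate(d, "x", "m", "y", n_boot = 400, seed = 99)
  expect_identical(f1$boots, f2$boots)
  expect_identical(c(f1$ci_low, f1$ci_high), c(f2$ci_low, f2$ci_high))
  expect_true(f1$ci_low <= f1$indirect && f1$indirect <= f1$ci_high)
  expect_true(f1$significant)

  fb <- mediate(d, "x", "m", "y", n_boot = 400, seed = 99, ci_type = "bca")
  expect_true(fb$ci_low <= fb$indirect && fb$indirect <= fb$ci_high)
})

test_that("CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    sp <- cohort_spec(n_hc = ceiling(n / 3), n_nci = ceiling(n / 3),
                      n_mci = n - 2 * ceiling(n / 3),
                      mediation_model = list(a = -0.4, b = 2, c_prime = -1,
                                             sd_m = 0.5, sd_y = 1),
                      effect_model = NULL, covariate_model = NULL, seed = 50)
    tab <- make_cohort(sp)
    f <- mediate(tab, "pvs_putamen", "alps_index", "moca", n_boot = 400,
                 seed = 50)
    f$ci_high - f$ci_low
  }, numeric(1))
  expect_true(widths[1] > widths[2] && widths[2] > widths[3])
  # quadrupling n should roughly halve the width
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.35)
})

test_that("planted coefficients are recovered from a large synthetic cohort", {
  sp <- cohort_spec(n_hc = 667, n_nci = 667, n_mci = 666,
                    mediation_model = list(a = -50, b = 0.004,
                                           c_prime = -0.012,
                                           sd_m = 5, sd_y = 0.002),
                    effect_model = NULL, covariate_model = NULL, seed = 2)
  tab <- make_cohort(sp)
  fit <- mediate(tab, "pvs_putamen", "alps_index", "moca", n_boot = 100,
                 seed = 2)
  est <- setNames(fit$paths$estimate, fit$paths$path)
  expect_equal(est[["a"]], -50, tolerance = 0.05)
  expect_equal(est[["b"]], 0.004, tolerance = 0.05)
  expect_equal(fit$indirect, -0.2, tolerance = 0.05)
})

test_that("inconsistent mediation suppresses the mediated proportion", {
  set.seed(43)
  n <- 400
  d <- data.frame(x = rnorm(n))
  d$m <- 0.8 * d$x + rnorm(n, sd = 0.3)
  d$y <- -1.2 * d$x + 1.1 * d$m + rnorm(n, sd = 0.3)   # indirect > 0, total < 0
  fit <- mediate(d, "x", "m", "y", n_boot = 100, seed = 43)
  expect_gt(fit$indirect, 0)
  expect_lt(fit$paths$estimate[fit$paths$path == "c"], 0)
  expect_true(is.na(fit$mediation_percent))
})

test_that("collinear exposure and mediator are rejected", {
  d <- data.frame(x = 1:20)
  d$m <- 2 * d$x
  d$y <- rnorm(20)
  expect_error(mediate(d, "x", "m", "y", n_boot = 10), "collinear")
  expect_error(mediate(d[1:5, ], "x", "y", "m", n_boot = 10), "complete cases")
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(44)
  d <- data.frame(x = rnorm(80))
  d$m <- 0.5 * d$x + rnorm(80, sd = 0.5)
  d$y <- 0.4 * d$m + rnorm(80, sd = 0.5)
  fit <- mediate(d, "x", "m", "y", n_boot = 100, seed = 3)
  td <- tidy(fit)
  expect_equal(td$path, c("a", "b", "c_prime", "c", "indirect"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(gl$n, 80L)
  expect_equal(gl$n_boot, 100)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
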