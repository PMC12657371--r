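#' Intraclass correlation for absolute agreement
#'
#' Single-measure intraclass correlation from a two-way model for absolute
#' agreement (the usual inter-/intra-rater reliability statistic for ROI
#' measurements such as the ALPS index). With row (subject), column (rater)
#' and error mean squares MSR, MSC, MSE from the two-way decomposition of an
#' n x k complete ratings matrix:
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' The 95% confidence interval uses the standard F-based interval with
#' Satterthwaite degrees of freedom. Missing cells are rejected (no
#' imputation).
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns; no missing cells, >= 5 subjects, >= 2 raters.
#' @param conf_level Confidence level for the interval.
#' @return An `icc_result` with `icc`, `ci_low`, `ci_high`, the mean squares,
#'   `n_subjects` and `n_raters`.
#' @export
#' @examples
#' r1 <- rnorm(30, 1.3, 0.1)
#' icc_absolute_agreement(cbind(r1, r1 + rnorm(30, 0, 0.02)))
icc_absolute_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  assert_that(is.numeric(ratings), "`ratings` must be numeric")
  assert_that(!anyNA(ratings), "missing cells are not allowed (no imputation)")
  n <- nrow(ratings)
  k <- ncol(ratings)
  assert_that(k >= 2, "need at least 2 raters")
  assert_that(n >= 5, "need at least 5 subjects")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (denom == 0) 1 else (msr - mse) / denom

  alpha <- 1 - conf_level
  if (mse == 0 && msc == mse) {
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  }
  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2],
         msr = msr, msc = msc, mse = mse,
         n_subjects = n, n_raters = k, conf_level = conf_level),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.3f (%d%% CI %.3f-%.3f), n = %d subjects x %d raters\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_subjects, x$n_raters))
  invisible(x)
}

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_subjects = x$n_subjects, n_raters = x$n_raters,
                 conf_level = x$conf_level)
}
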