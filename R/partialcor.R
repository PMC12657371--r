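#' Covariate-adjusted partial correlation
#'
#' Partial correlation of two variables given a covariate set, computed by
#' residualized Pearson correlation: both variables are regressed (OLS, with
#' intercept) on the covariates and the residuals are correlated. This is
#' algebraically identical to the inverse-correlation-matrix definition and
#' straightforward to verify against a brute-force oracle. Significance uses
#' t = r sqrt(df / (1 - r^2)) with df = n - 2 - k, two-sided.
#'
#' @param data Data frame holding all variables.
#' @param x,y Column names of the two variables.
#' @param covariates Character vector of covariate column names (may be
#'   empty, in which case the result is the plain Pearson correlation).
#' @return One-row tibble: `x`, `y`, `covariates`, `n`, `r`, `df`,
#'   `statistic`, `p_value`.
#' @export
#' @examples
#' d <- data.frame(a = rnorm(30), b = rnorm(30), age = rnorm(30))
#' partial_correlation(d, "a", "b", "age")
partial_correlation <- function(data, x, y, covariates = character()) {
  assert_that(all(c(x, y, covariates) %in% names(data)),
              "all variables must be columns of `data`")
  use <- stats::complete.cases(data[, c(x, y, covariates), drop = FALSE])
  d <- data[use, , drop = FALSE]
  n <- nrow(d)
  k <- length(covariates)
  xv <- as.numeric(d[[x]])
  yv <- as.numeric(d[[y]])
  if (k > 0) {
    fml <- stats::reformulate(covariates)
    C <- stats::model.matrix(fml, data = d)
    k <- ncol(C) - 1L                      # factors may expand
    assert_that(n > k + 2, "too few complete cases for the covariate set")
    qrC <- qr(C)
    assert_that(qrC$rank == ncol(C), "covariate matrix is rank deficient")
    rx <- stats::lm.fit(C, xv)$residuals
    ry <- stats::lm.fit(C, yv)$residuals
  } else {
    assert_that(n > 2, "need more than 2 complete cases")
    rx <- xv - mean(xv)
    ry <- yv - mean(yv)
  }
  floor_x <- 1e-10 * max(stats::sd(xv), .Machine$double.eps)
  floor_y <- 1e-10 * max(stats::sd(yv), .Machine$double.eps)
  assert_that(stats::sd(rx) > floor_x && stats::sd(ry) > floor_y,
              "zero residual variance; variable is collinear with covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(
    x = x, y = y,
    covariates = paste(covariates, collapse = "+"),
    n = n, r = r, df = df, statistic = tstat,
    p_value = 2 * stats::pt(-abs(tstat), df)
  )
}

#' Many partial correlations with FDR control
#'
#' Computes [partial_correlation()] for every (x, y) pair in the cross of
#' `x_vars` and `y_vars` with a shared covariate set, then attaches
#' Benjamini-Hochberg q-values within the declared families (a single family
#' by default). This is the engine behind the correlation heatmap relating
#' the ALPS index to regional PVS burden and to cognitive domains.
#'
#' @param data Data frame.
#' @param x_vars,y_vars Column-name vectors defining the pair grid.
#' @param covariates Shared covariate column names.
#' @param family Optional vector (length = number of pairs, recycled from a
#'   single value) labelling the FDR family of each pair, in the row order of
#'   the output (x varies fastest).
#' @return Tibble of pair results with a `q_value` column.
#' @export
partial_correlation_matrix <- function(data, x_vars, y_vars,
                                       covariates = character(),
                                       family = NULL) {
  grid <- tidyr::expand_grid(y = y_vars, x = x_vars)
  res <- purrr::map2_dfr(grid$x, grid$y, function(xx, yy)
    partial_correlation(data, xx, yy, covariates))
  fam <- family %||% "all"
  res$family <- rep_len(fam, nrow(res))
  res$q_value <- fdr_adjust(res$p_value, family = res$family)
  res
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up false-discovery-rate control applied separately within each
#' declared family of tests. q-values are monotone and never smaller than the
#' raw p-values.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param family Optional family label per p-value; `NULL` treats all
#'   p-values as one family.
#' @return Numeric vector of q-values.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_adjust <- function(pvalues, family = NULL) {
  assert_that(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  if (is.null(family)) family <- rep("all", length(pvalues))
  assert_that(length(family) == length(pvalues),
              "`family` must match `pvalues` in length")
  q <- pvalues
  for (f in unique(family)) {
    i <- family == f
    q[i] <- stats::p.adjust(pvalues[i], method = "BH")
  }
  q
}
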