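#' Percentile-bootstrap mediation analysis
#'
#' Decomposes the association between an exposure X and an outcome Y into the
#' indirect path through a mediator M and the direct remainder, with a shared
#' covariate set, by three OLS fits:
#' M ~ X + Z gives `a`; Y ~ X + M + Z gives `b` and the direct effect
#' `c_prime`; Y ~ X + Z gives the total effect `c`. The indirect effect is
#' `a * b`, and with identical covariates in all models the OLS identity
#' c = c_prime + a*b holds exactly. Inference on the indirect effect uses a
#' non-parametric subject-level bootstrap (rows resampled with replacement,
#' both models refit per replicate; default 5000 replicates) with a
#' percentile confidence interval; the indirect effect is declared
#' significant when the interval excludes zero. A bias-corrected and
#' accelerated (BCa) interval is available via `ci_type = "bca"`.
#'
#' The mediated proportion, 100 * indirect / c, is reported only under
#' consistent mediation (indirect and total effect of the same sign); it is
#' undefined (NA) otherwise.
#'
#' @param data Data frame with all variables.
#' @param x,m,y Column names of exposure, mediator and outcome.
#' @param covariates Character vector of covariate column names.
#' @param n_boot Bootstrap replicates.
#' @param conf_level Confidence level of the interval.
#' @param seed Integer seed for the bootstrap.
#' @param ci_type `"percentile"` (default) or `"bca"`.
#' @param standardize If `TRUE`, x, m and y are scaled to unit SD first, so
#'   the paths are standardized coefficients.
#' @return A `glymph_mediation` object; see [tidy.glymph_mediation()] and
#'   [glance.glymph_mediation()].
#' @export
#' @examples
#' d <- data.frame(x = rnorm(100))
#' d$m <- 0.5 * d$x + rnorm(100, sd = 0.3)
#' d$y <- 0.3 * d$x + 0.4 * d$m + rnorm(100, sd = 0.3)
#' fit <- mediate(d, "x", "m", "y", n_boot = 200, seed = 2)
#' glance(fit)
mediate <- function(data, x, m, y, covariates = character(),
                    n_boot = 5000L, conf_level = 0.95, seed = 1L,
                    ci_type = c("percentile", "bca"), standardize = FALSE) {
  ci_type <- match.arg(ci_type)
  assert_that(all(c(x, m, y, covariates) %in% names(data)),
              "all variables must be columns of `data`")
  seed <- normalize_seed(seed)
  vars <- c(x, m, y, covariates)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(d)
  assert_that(n >= 10 + length(covariates),
              "too few complete cases for mediation (need >= 10 + #covariates)")
  if (standardize) {
    for (v in c(x, m, y)) d[[v]] <- d[[v]] / stats::sd(d[[v]])
  }

  Z <- if (length(covariates)) {
    stats::model.matrix(stats::reformulate(covariates), data = d)[, -1, drop = FALSE]
  } else NULL
  xv <- as.numeric(d[[x]]); mv <- as.numeric(d[[m]]); yv <- as.numeric(d[[y]])
  Xm <- cbind(`(Intercept)` = 1, x = xv, Z)
  Xy <- cbind(`(Intercept)` = 1, x = xv, m = mv, Z)
  assert_that(qr(Xy)$rank == ncol(Xy),
              "exposure, mediator and covariates are collinear")

  fit_m <- stats::lm(mv ~ Xm - 1)
  fit_y <- stats::lm(yv ~ Xy - 1)
  fit_t <- stats::lm(yv ~ Xm - 1)
  coef_p <- function(fit, i) {
    s <- summary(fit)$coefficients
    c(est = s[i, 1], se = s[i, 2], p = s[i, 4])
  }
  pa <- coef_p(fit_m, 2)
  pb <- coef_p(fit_y, 3)
  pcp <- coef_p(fit_y, 2)
  pc <- coef_p(fit_t, 2)
  a <- pa[["est"]]; b <- pb[["est"]]
  c_prime <- pcp[["est"]]; c_total <- pc[["est"]]
  indirect <- a * b

  pivoted_coef <- function(fit, j) {
    co <- numeric(length(fit$pivot))
    co[fit$pivot] <- fit$coefficients
    co[j]
  }
  boot_indirect <- function(idx) {
    Xb <- Xm[idx, , drop = FALSE]
    fm <- stats::.lm.fit(Xb, mv[idx])
    if (fm$rank < ncol(Xb)) return(NULL)
    Xyb <- Xy[idx, , drop = FALSE]
    fy <- stats::.lm.fit(Xyb, yv[idx])
    if (fy$rank < ncol(Xyb)) return(NULL)
    pivoted_coef(fm, 2) * pivoted_coef(fy, 3)
  }
  set.seed(seed)
  boots <- numeric(n_boot)
  redraws <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      val <- boot_indirect(sample.int(n, n, replace = TRUE))
      if (!is.null(val)) break
      redraws <- redraws + 1L
      assert_that(redraws < 100 * n_boot, "bootstrap keeps hitting rank deficiency")
    }
    boots[i] <- val
  }
  alpha <- 1 - conf_level
  if (ci_type == "percentile") {
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  } else {
    z0 <- stats::qnorm(mean(boots < indirect))
    jack <- vapply(seq_len(n), function(i) {
      boot_indirect(setdiff(seq_len(n), i)) %||% NA_real_
    }, numeric(1))
    jm <- mean(jack, na.rm = TRUE)
    num <- sum((jm - jack)^3, na.rm = TRUE)
    den <- 6 * sum((jm - jack)^2, na.rm = TRUE)^1.5
    acc <- if (den == 0) 0 else num / den
    adj <- function(zq) stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    ci <- unname(stats::quantile(boots, c(adj(stats::qnorm(alpha / 2)),
                                          adj(stats::qnorm(1 - alpha / 2)))))
  }
  consistent <- is.finite(c_total) && c_total != 0 &&
    sign(indirect) == sign(c_total)
  structure(
    list(
      paths = tibble::tibble(
        path = c("a", "b", "c_prime", "c"),
        description = c("X -> M", "M -> Y | X", "X -> Y | M", "X -> Y (total)"),
        estimate = c(a, b, c_prime, c_total),
        std_error = c(pa[["se"]], pb[["se"]], pcp[["se"]], pc[["se"]]),
        p_value = c(pa[["p"]], pb[["p"]], pcp[["p"]], pc[["p"]])
      ),
      indirect = indirect, ci_low = ci[1], ci_high = ci[2],
      significant = ci[1] > 0 || ci[2] < 0,
      mediation_percent = if (consistent) 100 * indirect / c_total else NA_real_,
      boots = boots, n = n, n_boot = n_boot, redraws = redraws,
      seed = seed, conf_level = conf_level, ci_type = ci_type,
      x = x, m = m, y = y, covariates = covariates,
      standardize = standardize
    ),
    class = "glymph_mediation"
  )
}

#' @export
print.glymph_mediation <- function(x, ...) {
  cat(sprintf("<glymph_mediation> %s -> %s -> %s (n = %d, %d bootstrap reps)\n",
              x$x, x$m, x$y, x$n, x$n_boot))
  p <- x$paths
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-7s %-14s %10.4f  (p = %.4g)\n",
                p$path[i], p$description[i], p$estimate[i], p$p_value[i]))
  }
  cat(sprintf("  indirect a*b = %.4f, %d%% %s CI [%.4f, %.4f] -> %s\n",
              x$indirect, round(100 * x$conf_level), x$ci_type,
              x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  if (is.finite(x$mediation_percent %||% NA_real_)) {
    cat(sprintf("  mediated proportion = %.1f%%\n", x$mediation_percent))
  } else {
    cat("  mediated proportion undefined (inconsistent mediation)\n")
  }
  invisible(x)
}

#' Tidy a mediation fit
#'
#' @param x A `glymph_mediation`.
#' @param ... Unused.
#' @return Tibble of path coefficients (a, b, c_prime, c) plus the indirect
#'   effect row with its bootstrap confidence interval.
#' @method tidy glymph_mediation
#' @export
tidy.glymph_mediation <- function(x, ...) {
  dplyr::bind_rows(
    x$paths,
    tibble::tibble(path = "indirect", description = "a * b",
                   estimate = x$indirect, std_error = stats::sd(x$boots),
                   p_value = NA_real_)
  ) |>
    dplyr::mutate(
      ci_low = ifelse(.data$path == "indirect", x$ci_low, NA_real_),
      ci_high = ifelse(.data$path == "indirect", x$ci_high, NA_real_)
    )
}

#' Glance at a mediation fit
#'
#' @param x A `glymph_mediation`.
#' @param ... Unused.
#' @return One-row tibble with the indirect effect, its CI, significance,
#'   mediated proportion and bookkeeping (n, n_boot, seed, redraws).
#' @method glance glymph_mediation
#' @export
glance.glymph_mediation <- function(x, ...) {
  tibble::tibble(
    indirect = x$indirect, ci_low = x$ci_low, ci_high = x$ci_high,
    significant = x$significant, mediation_percent = x$mediation_percent,
    c_total = x$paths$estimate[x$paths$path == "c"],
    n = x$n, n_boot = x$n_boot, redraws = x$redraws, seed = x$seed,
    ci_type = x$ci_type
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @export
generics::tidy
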