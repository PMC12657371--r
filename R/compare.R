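#' Assumption-aware group comparison
#'
#' Compares a variable across groups the way clinical baseline tables are
#' built: continuous variables are tested for per-group normality
#' (Shapiro-Wilk, alpha 0.05) and homogeneity of variance (Levene on medians);
#' if both hold, a one-way ANOVA is used, otherwise the Kruskal-Wallis test.
#' Categorical variables get a Pearson chi-square test without continuity
#' correction. Pairwise group comparisons are Bonferroni-corrected: raw
#' pairwise p multiplied by the number of comparisons and capped at 1.
#'
#' @param values Vector of observations (numeric for continuous; factor,
#'   character or logical for categorical — numeric can be forced categorical
#'   via `type`).
#' @param groups Group label per observation (>= 2 groups).
#' @param type `"auto"`, `"continuous"` or `"categorical"`.
#' @param shapiro_alpha Per-group normality alpha for the test branch.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `normality_p` (minimum per-group Shapiro p), `levene_p`, and a `pairwise`
#'   list-column holding a tibble of Bonferroni-corrected pairwise p-values.
#' @export
#' @examples
#' sex <- rep(c(1, 0, 1, 0), c(19, 21, 61, 59))
#' grp <- rep(c("HC", "CSVD"), c(40, 120))
#' group_compare(sex, grp, type = "categorical")$p_value  # 0.715
group_compare <- function(values, groups,
                          type = c("auto", "continuous", "categorical"),
                          shapiro_alpha = 0.05) {
  type <- match.arg(type)
  assert_that(length(values) == length(groups), "lengths differ")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  lev <- levels(droplevels(groups))
  assert_that(length(lev) >= 2, "need at least two groups")
  if (type == "auto") {
    type <- if (is.numeric(values)) "continuous" else "categorical"
  }

  if (type == "categorical") {
    tabx <- table(groups, values)
    assert_that(ncol(tabx) >= 2,
                "categorical variable takes a single value; contingency table is degenerate")
    ct <- suppressWarnings(stats::chisq.test(tabx, correct = FALSE))
    pairwise <- pairwise_table(lev, function(g1, g2) {
      sub <- groups %in% c(g1, g2)
      t2 <- table(droplevels(groups[sub]), values[sub])
      if (ncol(t2) < 2) return(NA_real_)
      suppressWarnings(stats::chisq.test(t2, correct = FALSE))$p.value
    })
    return(tibble::tibble(
      test = "chi-square", statistic = unname(ct$statistic),
      df = unname(ct$parameter), p_value = ct$p.value,
      normality_p = NA_real_, levene_p = NA_real_, pairwise = list(pairwise)
    ))
  }

  counts <- table(groups)
  assert_that(all(counts >= 2), "each group needs >= 2 observations")
  sw <- vapply(lev, function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || length(unique(v)) == 1) return(0)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  lv <- car::leveneTest(values ~ groups, center = stats::median)[["Pr(>F)"]][1]
  normal <- all(sw > shapiro_alpha) && lv > shapiro_alpha

  if (normal) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    pairwise <- pairwise_table(lev, function(g1, g2) {
      sub <- groups %in% c(g1, g2)
      stats::t.test(values[sub] ~ droplevels(groups[sub]),
                    var.equal = TRUE)$p.value
    })
    tibble::tibble(
      test = "anova", statistic = an[["F value"]][1],
      df = an[["Df"]][1], p_value = an[["Pr(>F)"]][1],
      normality_p = min(sw), levene_p = lv, pairwise = list(pairwise)
    )
  } else {
    kw <- stats::kruskal.test(values ~ groups)
    pairwise <- pairwise_table(lev, function(g1, g2) {
      sub <- groups %in% c(g1, g2)
      suppressWarnings(stats::wilcox.test(values[sub] ~
                                          droplevels(groups[sub]))$p.value)
    })
    tibble::tibble(
      test = "kruskal-wallis", statistic = unname(kw$statistic),
      df = unname(kw$parameter), p_value = kw$p.value,
      normality_p = min(sw), levene_p = lv, pairwise = list(pairwise)
    )
  }
}

# All group pairs with Bonferroni-multiplied, capped p-values.
pairwise_table <- function(lev, pfun) {
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  raw <- vapply(seq_len(m), function(i) pfun(pairs[1, i], pairs[2, i]),
                numeric(1))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_raw = raw, p_bonferroni = pmin(raw * m, 1)
  )
}

#' Baseline characteristics table
#'
#' Applies [group_compare()] to a set of cohort columns, yielding the familiar
#' baseline-table summary (test used and p-value per variable).
#'
#' @param data Cohort tibble with a `group` column.
#' @param variables Column names to compare.
#' @param categorical Subset of `variables` to force categorical.
#' @return Tibble with one row per variable.
#' @export
compare_baseline <- function(data, variables, categorical = character()) {
  purrr::map_dfr(variables, function(v) {
    res <- group_compare(data[[v]], data$group,
                         type = if (v %in% categorical) "categorical" else "auto")
    dplyr::bind_cols(tibble::tibble(variable = v), res)
  })
}
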