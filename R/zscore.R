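#' Cognitive domain to test-column mapping
#'
#' Default assignment of raw test columns to cognitive domains: memory (AVLT),
#' executive function (TMT-B), processing speed (TMT-A), visuospatial function
#' (10-point clock drawing) and language (Boston Naming Test). The two
#' TMT-derived domains are timed (higher raw score = worse) and are inverted
#' after standardization.
#'
#' @format Named character vector: domain name to cohort column.
#' @export
DOMAIN_TESTS <- c(memory = "avlt", executive = "tmt_b",
                  processing_speed = "tmt_a", visuospatial = "cdt10",
                  language = "bnt")

#' Healthy-control referenced cognitive z-scores
#'
#' Standardizes each raw cognitive test score against the healthy-control
#' subgroup: z = (score - mean(HC)) / sd(HC), using the sample SD of the
#' reference group. Domains derived from timed tests (executive function from
#' TMT-B, processing speed from TMT-A) are then multiplied by -1 so that
#' higher z always means better performance. By construction the HC subgroup
#' has mean 0 and SD 1 in every domain.
#'
#' @param table Cohort tibble with a `group` column and the raw test columns.
#' @param reference_group Group label used as the reference (default `"HC"`).
#' @param tests Named character vector mapping domain name to test column.
#' @param inverted Domains whose z is sign-flipped.
#' @return The input tibble with added `z_<domain>` columns.
#' @export
#' @examples
#' tab <- make_cohort(cohort_spec(n_hc = 10, n_nci = 5, n_mci = 5))
#' z <- zscore_cognition(tab)
#' colMeans(z[z$group == "HC", paste0("z_", names(DOMAIN_TESTS))])
zscore_cognition <- function(table, reference_group = "HC",
                             tests = DOMAIN_TESTS,
                             inverted = c("executive", "processing_speed")) {
  assert_that("group" %in% names(table), "`table` needs a `group` column")
  ref <- table$group == reference_group
  assert_that(sum(ref) >= 2,
              sprintf("reference group '%s' needs >= 2 subjects", reference_group))
  missing_tests <- setdiff(unname(tests), names(table))
  assert_that(length(missing_tests) == 0,
              paste("missing test columns:", paste(missing_tests, collapse = ", ")))
  for (dom in names(tests)) {
    col <- tests[[dom]]
    mu <- mean(table[[col]][ref])
    sd_ref <- stats::sd(table[[col]][ref])
    assert_that(is.finite(sd_ref) && sd_ref > 0,
                sprintf("reference group SD of test '%s' is zero; cannot standardize", col))
    z <- (table[[col]] - mu) / sd_ref
    if (dom %in% inverted) z <- -z
    table[[paste0("z_", dom)]] <- z
  }
  table
}
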