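GROUP_LEVELS <- c("HC", "CSVD-NCI", "CSVD-MCI")

#' Specify a synthetic cohort
#'
#' Describes a three-group cohort (healthy controls, CSVD without cognitive
#' impairment, CSVD with mild cognitive impairment) whose rows are generated
#' by a linear structural model with a planted mediation path
#' X -> M -> Y, where X is putamen PVS volume fraction, M the ALPS index and
#' Y the MoCA score:
#' \deqn{M = \alpha_M[g] + aX + w_M'Z + \varepsilon_M}
#' \deqn{Y = \alpha_Y[g] + c'X + bM + w_Y'Z + \varepsilon_Y}
#' Group intercepts are chosen so marginal group means follow `effect_model`;
#' with `effect_model = NULL` the generator reduces to the bare structural
#' equations (zero intercepts, X standard normal), which is convenient for
#' exact algebraic checks.
#'
#' The default group sizes (40/52/68) and group means for ALPS, MoCA, age and
#' risk-factor prevalences mirror the scale of a typical single-center CSVD
#' cohort; regional PVS volume-fraction means are plausible values chosen
#' once for the generator (no per-subject reference distributions exist).
#'
#' @param n_hc,n_nci,n_mci Positive subject counts per group.
#' @param mediation_model List with path coefficients `a`, `b`, `c_prime` and
#'   noise SDs `sd_m`, `sd_y` (both >= 0).
#' @param effect_model `NULL`, or a list with per-group `alps` means/SDs,
#'   `moca` means, and a `pvs` table of regional vf means/SDs (see
#'   `default_effect_model()`); partial lists are completed with defaults.
#' @param covariate_model `NULL` (no covariates in the structural equations),
#'   `"default"` for the built-in demographics/risk-factor generator with
#'   small regression weights, or a custom list (see
#'   `default_covariate_model()`).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 40L, n_nci = 52L, n_mci = 68L,
                        mediation_model = list(a = -0.15, b = 6, c_prime = -2,
                                               sd_m = 0.08, sd_y = 2.5),
                        effect_model = default_effect_model(),
                        covariate_model = "default",
                        seed = 1L) {
  counts <- c(n_hc, n_nci, n_mci)
  assert_that(all(counts >= 1), "group counts must be positive")
  mm <- utils::modifyList(list(a = -0.15, b = 6, c_prime = -2,
                               sd_m = 0.08, sd_y = 2.5), mediation_model)
  assert_that(mm$sd_m >= 0 && mm$sd_y >= 0, "noise SDs must be non-negative")
  if (!is.null(effect_model)) {
    effect_model <- utils::modifyList(default_effect_model(), effect_model)
  }
  if (identical(covariate_model, "default")) covariate_model <- default_covariate_model()
  structure(
    list(n = stats::setNames(as.integer(counts), GROUP_LEVELS),
         mediation_model = mm, effect_model = effect_model,
         covariate_model = covariate_model, seed = normalize_seed(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_effect_model <- function() {
  gm <- function(...) stats::setNames(c(...), GROUP_LEVELS)
  list(
    alps = list(mean = gm(1.39, 1.29, 1.23), sd = gm(0.14, 0.11, 0.11)),
    moca = list(mean = gm(25.98, 25.25, 19.82)),
    pvs = list(
      caudate = list(mean = gm(0.30, 0.45, 0.50), sd = 0.12),
      putamen = list(mean = gm(0.35, 0.55, 0.60), sd = 0.15),
      pallidum = list(mean = gm(0.12, 0.14, 0.14), sd = 0.05),
      amygdala = list(mean = gm(0.10, 0.11, 0.11), sd = 0.04),
      thalamus = list(mean = gm(0.25, 0.30, 0.32), sd = 0.10),
      hippocampus = list(mean = gm(0.20, 0.24, 0.30), sd = 0.09)
    ),
    cognition = list(
      avlt = list(mean = gm(45, 40, 32), sd = 8),
      tmt_a = list(mean = gm(55, 65, 85), sd = 15),
      tmt_b = list(mean = gm(130, 160, 210), sd = 30),
      cdt10 = list(mean = gm(8.5, 8.0, 6.5), sd = 1.2),
      bnt = list(mean = gm(24, 23, 20), sd = 3)
    )
  )
}

#' @rdname cohort_spec
#' @export
default_covariate_model <- function() {
  gm <- function(...) stats::setNames(c(...), GROUP_LEVELS)
  list(
    age = list(mean = gm(60.18, 62.38, 64.69), sd = gm(4.57, 6.96, 6.62)),
    education = list(mean = gm(9.43, 9.09, 8.10), sd = gm(4.10, 3.85, 3.80)),
    bmi = list(mean = gm(23.77, 23.78, 23.89), sd = gm(2.28, 2.55, 3.02)),
    male_p = gm(0.475, 0.5385, 0.4853),
    hypertension_p = gm(0.35, 0.6346, 0.6618),
    diabetes_p = gm(0.15, 0.1731, 0.1765),
    hypercholesterolemia_p = gm(0.25, 0.2885, 0.2794),
    smoking_p = gm(0.125, 0.3077, 0.3088),
    lacunes_p = gm(0, 0.2692, 0.2353),
    cmbs_p = gm(0, 0.4231, 0.4853),
    bg_epvs_p = gm(0, 0.4808, 0.7059),
    fazekas_range = list(HC = 0:2, `CSVD-NCI` = 2:5, `CSVD-MCI` = 3:6),
    # regression weights of covariates into the mediator and outcome
    weights_m = c(age = -0.003),
    weights_y = c(age = -0.05, education = 0.12)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject from a [cohort_spec()]: group label, demographics
#' and vascular risk factors (when a covariate model is present), imaging
#' covariate grades, raw cognitive scores, regional PVS volume fractions (the
#' basal-ganglia value is the sum of its caudate/putamen/pallidum/amygdala
#' subdivisions, consistent with a shared whole-brain denominator), the ALPS
#' index, and the MoCA outcome — the latter two produced by the planted
#' structural mediation model. Bit-reproducible under a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject; the generating parameters are
#'   attached as attribute `"ground_truth"`.
#' @export
#' @examples
#' tab <- make_cohort(cohort_spec(n_hc = 5, n_nci = 5, n_mci = 5))
#' dplyr::count(tab, group)
make_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  set.seed(spec$seed)
  group <- factor(rep(GROUP_LEVELS, times = spec$n), levels = GROUP_LEVELS)
  n <- length(group)
  mm <- spec$mediation_model
  em <- spec$effect_model
  cm <- spec$covariate_model
  per_group <- function(mean, sd) {
    stats::rnorm(n, mean = mean[as.character(group)],
                 sd = if (length(sd) == 1) sd else sd[as.character(group)])
  }
  tab <- tibble::tibble(subject_id = sprintf("sub-%03d", seq_len(n)),
                        group = group)

  if (!is.null(cm)) {
    bern <- function(p) stats::rbinom(n, 1L, p[as.character(group)])
    tab$age <- round(per_group(cm$age$mean, cm$age$sd), 1)
    tab$sex <- bern(cm$male_p)                     # male = 1
    tab$education <- round(pmax(per_group(cm$education$mean, cm$education$sd), 0), 1)
    tab$hypertension <- bern(cm$hypertension_p)
    tab$diabetes <- bern(cm$diabetes_p)
    tab$hypercholesterolemia <- bern(cm$hypercholesterolemia_p)
    tab$smoking <- bern(cm$smoking_p)
    tab$bmi <- round(per_group(cm$bmi$mean, cm$bmi$sd), 1)
    tab$fazekas <- vapply(as.character(group), function(g)
      sample(cm$fazekas_range[[g]], 1L), integer(1))
    tab$lacunes <- bern(cm$lacunes_p)
    tab$cmbs <- bern(cm$cmbs_p)
    tab$bg_epvs_grade <- bern(cm$bg_epvs_p)
  }

  if (!is.null(em)) {
    for (rg in names(em$pvs)) {
      tab[[paste0("pvs_", rg)]] <-
        pmax(per_group(em$pvs[[rg]]$mean, em$pvs[[rg]]$sd), 0)
    }
    tab$pvs_bg <- tab$pvs_caudate + tab$pvs_putamen +
      tab$pvs_pallidum + tab$pvs_amygdala
    x <- tab$pvs_putamen
    x_mean <- em$pvs$putamen$mean
    alpha_m <- em$alps$mean - mm$a * x_mean
    alpha_y <- em$moca$mean - mm$c_prime * x_mean - mm$b * em$alps$mean
  } else {
    x <- stats::rnorm(n)
    tab$pvs_putamen <- x
    alpha_m <- alpha_y <- stats::setNames(rep(0, 3), GROUP_LEVELS)
  }

  wm <- wy <- rep(0, n)
  if (!is.null(cm)) {
    for (v in names(cm$weights_m)) wm <- wm + cm$weights_m[[v]] *
        (tab[[v]] - mean(tab[[v]]))
    for (v in names(cm$weights_y)) wy <- wy + cm$weights_y[[v]] *
        (tab[[v]] - mean(tab[[v]]))
  }
  m <- alpha_m[as.character(group)] + mm$a * x + wm +
    stats::rnorm(n, sd = mm$sd_m)
  y <- alpha_y[as.character(group)] + mm$c_prime * x + mm$b * m + wy +
    stats::rnorm(n, sd = mm$sd_y)
  tab$alps_index <- unname(m)
  tab$moca <- unname(y)

  if (!is.null(em)) {
    for (ts in names(em$cognition)) {
      cg <- em$cognition[[ts]]
      tab[[ts]] <- pmax(per_group(cg$mean, cg$sd), 0)
    }
    tab$cdr <- ifelse(group == "CSVD-MCI", 0.5, 0)
  }
  attr(tab, "ground_truth") <- list(
    a = mm$a, b = mm$b, c_prime = mm$c_prime,
    indirect = mm$a * mm$b, sd_m = mm$sd_m, sd_y = mm$sd_y,
    seed = spec$seed, n = spec$n
  )
  tab
}
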