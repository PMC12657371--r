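#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]. All
#' settings have working defaults that exercise the full pipeline on bundled
#' synthetic phantoms and a synthetic cohort; any part can be overridden, and
#' a YAML file with the same keys can be loaded via [read_pipeline_config()].
#'
#' @param dwi A [dwi_phantom_spec()] (or `NULL` to skip the ALPS stage).
#' @param pvs A [pvs_phantom_spec()] (or `NULL` to skip the PVS stage).
#' @param cohort A [cohort_spec()].
#' @param roi_table ROI tibble for [compute_alps()]; defaults to the phantom
#'   block centroids.
#' @param frangi A [frangi_params()].
#' @param segmentation List with `threshold` and `min_cluster_voxels`.
#' @param covariates Named list of covariate sets: `alps_pvs` (demographics +
#'   vascular risk factors), `alps_cognition` (adds imaging markers),
#'   `mediation`.
#' @param fdr_families Named list mapping family label to the y-variables in
#'   that family for the correlation stage.
#' @param mediation List with `x`, `m`, `y`, `n_boot`, `ci_type`.
#' @param seed Global seed; recorded in every output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dwi = dwi_phantom_spec(grid_shape = c(24L, 24L, 24L),
                                                   layout = "alps_oracle"),
                            pvs = pvs_phantom_spec(),
                            cohort = cohort_spec(),
                            roi_table = NULL,
                            frangi = frangi_params(),
                            segmentation = list(threshold = 0.1,
                                                min_cluster_voxels = 3L),
                            covariates = NULL,
                            fdr_families = NULL,
                            mediation = list(x = "pvs_putamen", m = "alps_index",
                                             y = "moca", n_boot = 1000L,
                                             ci_type = "percentile"),
                            seed = 1L) {
  vrf <- c("hypertension", "diabetes", "hypercholesterolemia", "smoking", "bmi")
  demo <- c("age", "sex", "education")
  imaging <- c("fazekas", "lacunes", "cmbs", "bg_epvs_grade")
  covariates <- utils::modifyList(list(
    alps_pvs = c(demo, vrf),
    alps_cognition = c(demo, vrf, imaging),
    mediation = c(demo, vrf)
  ), covariates %||% list())
  fdr_families <- fdr_families %||% list(
    alps_vs_pvs = c("pvs_bg", "pvs_caudate", "pvs_putamen", "pvs_pallidum",
                    "pvs_amygdala", "pvs_thalamus", "pvs_hippocampus"),
    alps_vs_cognition = c("moca", "z_memory", "z_executive",
                          "z_processing_speed", "z_visuospatial", "z_language")
  )
  cfg <- list(dwi = dwi, pvs = pvs, cohort = cohort, roi_table = roi_table,
              frangi = frangi, segmentation = segmentation,
              covariates = covariates, fdr_families = fdr_families,
              mediation = mediation, seed = normalize_seed(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  assert_that(inherits(cfg$cohort, "cohort_spec"), "`cohort` must be a cohort_spec")
  if (!is.null(cfg$dwi)) {
    assert_that(inherits(cfg$dwi, "dwi_phantom_spec"),
                "`dwi` must be a dwi_phantom_spec or NULL")
    if (!is.null(cfg$roi_table)) {
      assert_that(all(c("fiber_type", "hemisphere", "x", "y", "z") %in%
                      names(cfg$roi_table)), "invalid `roi_table` columns")
    }
  }
  if (!is.null(cfg$pvs)) {
    assert_that(inherits(cfg$pvs, "pvs_phantom_spec"),
                "`pvs` must be a pvs_phantom_spec or NULL")
  }
  med <- cfg$mediation
  assert_that(all(c("x", "m", "y") %in% names(med)),
              "`mediation` needs x, m and y variable names")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Reads scalar settings (seed, segmentation, Frangi parameters, covariate
#' sets, FDR families, mediation variables, cohort sizes and mediation-model
#' coefficients) from a YAML file and completes them with the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$segmentation)) args$segmentation <- y$segmentation
  if (!is.null(y$frangi)) args$frangi <- do.call(frangi_params, y$frangi)
  if (!is.null(y$covariates)) args$covariates <- y$covariates
  if (!is.null(y$fdr_families)) args$fdr_families <- y$fdr_families
  if (!is.null(y$mediation)) args$mediation <- y$mediation
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$dwi)) args$dwi <- do.call(dwi_phantom_spec, y$dwi)
  if (!is.null(y$roi_table)) args$roi_table <- read_roi_table(y$roi_table)
  do.call(pipeline_config, args)
}

#' Run the full glymphatic analysis pipeline
#'
#' Executes the stages end to end on the configured inputs:
#' simulate (phantoms + cohort) -> ALPS (tensor fit, ROI extraction, index)
#' -> PVS (non-local means, EPC, Frangi, segmentation, volume fractions)
#' -> statistics (HC-referenced z-scores, baseline comparisons,
#' covariate-adjusted partial correlations with per-family FDR)
#' -> mediation. Every stage writes a tidy CSV into `out_dir`, and
#' `summary.json` collects the headline statistics together with the seed and
#' a hash of the configuration, making reruns byte-comparable.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing and returns results only.
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with `cohort`, `alps`, `pvs_vf`, `baseline`,
#'   `correlations`, `mediation` (a `glymph_mediation`), `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  validate_pipeline_config(config)
  seed <- normalize_seed(seed %||% config$seed)
  t0 <- Sys.time()
  log_stage <- function(stage, t_start) {
    message(sprintf("[glymphkit] %-9s %.2fs", stage,
                    as.numeric(Sys.time() - t_start, units = "secs")))
  }

  # -- simulate ---------------------------------------------------------------
  ts <- Sys.time()
  cohort_sp <- config$cohort
  cohort_sp$seed <- seed
  cohort <- make_cohort(cohort_sp)
  results <- list()

  # -- alps -------------------------------------------------------------------
  if (!is.null(config$dwi)) {
    dwi_sp <- config$dwi
    dwi_sp$seed <- seed
    ph <- make_dwi_phantom(dwi_sp)
    log_stage("simulate", ts)
    ts <- Sys.time()
    tf <- fit_tensors(ph$dwi)
    roi <- config$roi_table %||% phantom_roi_table(dwi_sp)
    results$alps <- compute_alps(tf, roi)
    log_stage("alps", ts)
  } else {
    log_stage("simulate", ts)
  }

  # -- pvs --------------------------------------------------------------------
  if (!is.null(config$pvs)) {
    ts <- Sys.time()
    pvs_sp <- config$pvs
    pvs_sp$seed <- seed
    phantom <- make_pvs_phantom(pvs_sp)
    t1f <- nlm_filter(phantom$pair$t1w)
    t2f <- nlm_filter(phantom$pair$t2w)
    epc <- compute_epc(structural_pair(t1f, t2f,
                                       voxel_size = phantom$pair$voxel_size))
    vmap <- frangi_vesselness(epc, config$frangi)
    seg <- segment_pvs(vmap, phantom$atlas$tissue,
                       threshold = config$segmentation$threshold,
                       min_cluster_voxels = config$segmentation$min_cluster_voxels)
    results$pvs_vf <- pvs_volume_fraction(seg, phantom$atlas)
    results$pvs_truth <- phantom$truth_mask
    results$pvs_mask <- seg
    log_stage("pvs", ts)
  }

  # -- stats ------------------------------------------------------------------
  ts <- Sys.time()
  cohort <- zscore_cognition(cohort)
  results$cohort <- cohort
  baseline_vars <- intersect(
    c("age", "sex", "education", "hypertension", "diabetes",
      "hypercholesterolemia", "smoking", "bmi", "moca", "alps_index",
      "pvs_bg", "pvs_putamen"), names(cohort))
  categorical <- c("sex", "hypertension", "diabetes", "hypercholesterolemia",
                   "smoking")
  results$baseline <- compare_baseline(cohort, baseline_vars, categorical)

  csvd <- dplyr::filter(cohort, .data$group != "HC")
  fams <- config$fdr_families
  cors <- purrr::imap_dfr(fams, function(yvars, fam) {
    yvars <- intersect(yvars, names(csvd))
    covs <- if (fam == "alps_vs_cognition")
      config$covariates$alps_cognition else config$covariates$alps_pvs
    covs <- intersect(covs, names(csvd))
    partial_correlation_matrix(csvd, x_vars = "alps_index", y_vars = yvars,
                               covariates = covs, family = fam)
  })
  results$correlations <- cors
  log_stage("stats", ts)

  # -- mediate ----------------------------------------------------------------
  ts <- Sys.time()
  med <- config$mediation
  results$mediation <- mediate(
    csvd, med$x, med$m, med$y,
    covariates = intersect(config$covariates$mediation, names(csvd)),
    n_boot = med$n_boot %||% 5000L,
    ci_type = med$ci_type %||% "percentile",
    seed = seed
  )
  log_stage("mediate", ts)

  cfg_hash <- rlang::hash(config)
  results$summary <- list(
    seed = seed,
    config_hash = cfg_hash,
    alps = if (!is.null(results$alps)) as.list(results$alps[1, ]),
    mediation = as.list(glance(results$mediation)),
    n_subjects = nrow(cohort),
    elapsed_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {
      df$seed <- seed
      df$config_hash <- cfg_hash
      df
    }
    utils::write.csv(stamp(as.data.frame(cohort)),
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    if (!is.null(results$alps))
      utils::write.csv(stamp(results$alps), file.path(out_dir, "alps.csv"),
                       row.names = FALSE)
    if (!is.null(results$pvs_vf))
      utils::write.csv(stamp(results$pvs_vf), file.path(out_dir, "pvs_vf.csv"),
                       row.names = FALSE)
    utils::write.csv(stamp(results$baseline[, setdiff(names(results$baseline),
                                                      "pairwise")]),
                     file.path(out_dir, "baseline.csv"), row.names = FALSE)
    utils::write.csv(stamp(results$correlations),
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(stamp(tidy(results$mediation)),
                     file.path(out_dir, "mediation.csv"), row.names = FALSE)
    summary_clean <- results$summary
    summary_clean$elapsed_sec <- NULL   # keep reruns byte-identical
    jsonlite::write_json(summary_clean, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
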