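#' Structural T1w/T2w pair
#'
#' Container for co-registered T1-weighted and T2-weighted volumes on a common
#' grid; input to the enhanced PVS contrast stage.
#'
#' @param t1w,t2w 3D numeric arrays of identical shape, finite.
#' @param voxel_size Voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix.
#' @return A `structural_pair`.
#' @export
structural_pair <- function(t1w, t2w, voxel_size = c(1, 1, 1), affine = NULL) {
  assert_that(length(dim(t1w)) == 3 && identical(dim(t1w), dim(t2w)),
              "`t1w` and `t2w` must be 3D arrays of identical shape")
  assert_that(all(is.finite(t1w)) && all(is.finite(t2w)),
              "intensities must be finite")
  structure(
    list(t1w = t1w, t2w = t2w, voxel_size = as.numeric(voxel_size),
         affine = affine %||% diag(c(voxel_size, 1))),
    class = "structural_pair"
  )
}

# Region codes for the synthetic subcortical atlas. BG aggregates caudate,
# putamen, pallidum and amygdala (the study's BG subdivision list).
PVS_REGIONS <- c("caudate", "putamen", "pallidum", "amygdala",
                 "thalamus", "hippocampus")
BG_SUBDIVISIONS <- c("caudate", "putamen", "pallidum", "amygdala")

#' Synthetic subcortical atlas
#'
#' Builds a box-shaped stand-in for a subcortical segmentation: six nuclei
#' (caudate, putamen, pallidum, amygdala, thalamus, hippocampus), coded
#' separately per hemisphere, inside a GM+WM tissue mask. Purely synthetic
#' geometry for phantom work; it carries no anatomical shape information.
#'
#' @param grid_shape Voxels per axis (x splits hemispheres).
#' @param voxel_size mm per axis.
#' @return A `pvs_atlas`: integer `labels` array, logical `tissue` mask,
#'   `lookup` tibble (region, hemisphere, code) and the voxel geometry.
#' @export
synthetic_atlas <- function(grid_shape = c(40L, 40L, 32L), voxel_size = c(1, 1, 1)) {
  grid_shape <- as.integer(grid_shape)
  assert_that(all(grid_shape >= c(24, 24, 16)),
              "atlas grid must be at least 24 x 24 x 16 voxels")
  labels <- array(0L, dim = grid_shape)
  frac <- function(f, n) pmax(1L, pmin(n, as.integer(round(f * n))))
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  tissue <- array(FALSE, dim = grid_shape)
  tissue[frac(.08, nx):frac(.95, nx), frac(.08, ny):frac(.95, ny),
         frac(.12, nz):frac(.92, nz)] <- TRUE

  xr <- list(left = frac(.12, nx):frac(.42, nx), right = frac(.58, nx):frac(.88, nx))
  yb <- list(frac(.10, ny):frac(.30, ny), frac(.36, ny):frac(.56, ny),
             frac(.62, ny):frac(.82, ny))
  zb <- list(lower = frac(.16, nz):frac(.42, nz), upper = frac(.54, nz):frac(.84, nz))
  layout <- list(
    caudate = list(yb[[1]], zb$upper), putamen = list(yb[[2]], zb$upper),
    pallidum = list(yb[[3]], zb$upper), amygdala = list(yb[[1]], zb$lower),
    thalamus = list(yb[[2]], zb$lower), hippocampus = list(yb[[3]], zb$lower)
  )
  lookup <- tidyr::expand_grid(region = PVS_REGIONS,
                               hemisphere = c("left", "right"))
  lookup$code <- seq_len(nrow(lookup)) + 10L
  for (i in seq_len(nrow(lookup))) {
    reg <- layout[[lookup$region[i]]]
    labels[xr[[lookup$hemisphere[i]]], reg[[1]], reg[[2]]] <- lookup$code[i]
  }
  structure(
    list(labels = labels, tissue = tissue, lookup = lookup,
         voxel_size = as.numeric(voxel_size)),
    class = "pvs_atlas"
  )
}

#' @export
print.pvs_atlas <- function(x, ...) {
  cat(sprintf("<pvs_atlas> %s grid, %d regions, %d tissue voxels\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$lookup), sum(x$tissue)))
  invisible(x)
}

# Logical mask of voxel centers inside a finite cylinder (center-of-voxel
# membership: axial projection within [0, L], radial distance <= radius).
voxelize_cylinder <- function(dim3, voxel_size, start, end, radius) {
  ax <- voxel_centers(dim3, voxel_size)
  coords <- cbind(
    rep(ax[[1]], times = dim3[2] * dim3[3]),
    rep(rep(ax[[2]], each = dim3[1]), times = dim3[3]),
    rep(ax[[3]], each = dim3[1] * dim3[2])
  )
  u <- end - start
  L <- sqrt(sum(u^2))
  assert_that(L > 0, "cylinder endpoints coincide")
  u <- u / L
  rel <- sweep(coords, 2, start)
  t_ax <- rel %*% u
  rad2 <- rowSums(rel^2) - t_ax^2
  array(t_ax >= 0 & t_ax <= L & rad2 <= radius^2 + 1e-12, dim = dim3)
}

#' Specify a structural PVS phantom
#'
#' Describes a T1w/T2w phantom containing tubular perivascular spaces of known
#' geometry inside labelled subcortical nuclei. Each tube is a finite cylinder
#' (start/end in world mm, radius in mm) tagged with the region and hemisphere
#' it must lie in. PVS appear dark on T1w and bright on T2w, so tubes lower
#' T1 intensity and raise T2 intensity by the stated decrements; Gaussian
#' noise of `noise_sd` is added to both channels (magnitude statistics are
#' near-Gaussian at structural-image SNR).
#'
#' The default tube set is the package's standard test phantom: radii 1-2 mm,
#' 30% intensity contrast, noise 5% of the background intensity.
#'
#' @param atlas A [synthetic_atlas()] (also fixes grid and voxel size).
#' @param tubes List of `list(start =, end =, radius =, region =, hemisphere =)`;
#'   `NULL` for the standard set, `list()` for none.
#' @param intensity_model List with `t1_bg`, `t2_bg`, `t1_decrement`,
#'   `t2_increment`, `noise_sd`.
#' @param seed Integer seed for the noise generator.
#' @return A `pvs_phantom_spec`.
#' @export
pvs_phantom_spec <- function(atlas = synthetic_atlas(),
                             tubes = NULL,
                             intensity_model = list(t1_bg = 100, t2_bg = 100,
                                                    t1_decrement = 30,
                                                    t2_increment = 30,
                                                    noise_sd = 5),
                             seed = 1L) {
  assert_that(inherits(atlas, "pvs_atlas"), "`atlas` must be a pvs_atlas")
  im <- utils::modifyList(list(t1_bg = 100, t2_bg = 100, t1_decrement = 30,
                               t2_increment = 30, noise_sd = 5),
                          intensity_model)
  assert_that(im$noise_sd >= 0, "`noise_sd` must be non-negative")
  if (is.null(tubes)) tubes <- default_tubes(atlas)
  min_r <- 0.5 * min(atlas$voxel_size)
  for (tb in tubes) {
    assert_that(tb$radius >= min_r,
                sprintf("tube radius %.2f mm is below half the voxel size", tb$radius))
  }
  structure(
    list(atlas = atlas, tubes = tubes, intensity_model = im,
         seed = normalize_seed(seed)),
    class = "pvs_phantom_spec"
  )
}

# Standard tube set: a few axial/oblique cylinders inside putamen and caudate.
default_tubes <- function(atlas) {
  ctr <- function(region, hemisphere) {
    idx <- which(atlas$labels == atlas$lookup$code[
      atlas$lookup$region == region & atlas$lookup$hemisphere == hemisphere])
    pos <- arrayInd(idx, dim(atlas$labels))
    lo <- (apply(pos, 2, min) - 1) * atlas$voxel_size
    hi <- (apply(pos, 2, max) - 1) * atlas$voxel_size
    list(lo = lo, hi = hi, mid = (lo + hi) / 2)
  }
  lp <- ctr("putamen", "left"); rp <- ctr("putamen", "right")
  lc <- ctr("caudate", "left")
  pad <- 1
  list(
    list(start = c(lp$mid[1] - 3, lp$mid[2], lp$lo[3] + pad),
         end = c(lp$mid[1] - 3, lp$mid[2], lp$hi[3] - pad),
         radius = 1.0, region = "putamen", hemisphere = "left"),
    list(start = c(lp$mid[1] + 3, lp$lo[2] + pad, lp$mid[3]),
         end = c(lp$mid[1] + 3, lp$hi[2] - pad, lp$mid[3]),
         radius = 1.5, region = "putamen", hemisphere = "left"),
    list(start = c(rp$mid[1], rp$mid[2], rp$lo[3] + pad),
         end = c(rp$mid[1], rp$mid[2], rp$hi[3] - pad),
         radius = 1.2, region = "putamen", hemisphere = "right"),
    list(start = c(lc$mid[1], lc$mid[2], lc$lo[3] + pad),
         end = c(lc$mid[1], lc$mid[2], lc$hi[3] - pad),
         radius = 2.0, region = "caudate", hemisphere = "left")
  )
}

#' Generate a structural PVS phantom
#'
#' Renders the phantom described by a [pvs_phantom_spec()]: uniform background
#' T1w/T2w intensities, tube voxels (center-of-voxel-inside-cylinder rule)
#' darkened on T1w and brightened on T2w, then channel-wise Gaussian noise.
#' Tubes extending beyond the volume, or outside their declared region, are
#' rejected.
#'
#' @param spec A [pvs_phantom_spec()].
#' @return A list: `pair` ([structural_pair()]), `atlas`, `truth_mask`
#'   (logical ground-truth PVS array) and `tube_table` (tibble of tube
#'   geometry with analytic cylinder volumes in mm^3).
#' @export
make_pvs_phantom <- function(spec) {
  assert_that(inherits(spec, "pvs_phantom_spec"), "`spec` must be a pvs_phantom_spec")
  atlas <- spec$atlas
  d <- dim(atlas$labels)
  vs <- atlas$voxel_size
  extent_hi <- (d - 1) * vs
  truth <- array(FALSE, dim = d)
  rows <- list()
  for (i in seq_along(spec$tubes)) {
    tb <- spec$tubes[[i]]
    for (p in list(tb$start, tb$end)) {
      assert_that(all(p >= -vs / 2) && all(p <= extent_hi + vs / 2),
                  "tube endpoint lies outside the atlas extent")
    }
    m <- voxelize_cylinder(d, vs, tb$start, tb$end, tb$radius)
    code <- atlas$lookup$code[atlas$lookup$region == tb$region &
                              atlas$lookup$hemisphere == tb$hemisphere]
    assert_that(length(code) == 1, sprintf("unknown region '%s'", tb$region))
    assert_that(all(atlas$labels[m] == code),
                sprintf("tube %d leaves its declared region (%s %s)",
                        i, tb$hemisphere, tb$region))
    truth <- truth | m
    L <- sqrt(sum((tb$end - tb$start)^2))
    rows[[i]] <- tibble::tibble(
      tube = i, region = tb$region, hemisphere = tb$hemisphere,
      radius = tb$radius, length = L,
      analytic_volume = pi * tb$radius^2 * L,
      voxel_count = sum(m)
    )
  }
  im <- spec$intensity_model
  t1 <- array(im$t1_bg, dim = d); t1[truth] <- im$t1_bg - im$t1_decrement
  t2 <- array(im$t2_bg, dim = d); t2[truth] <- im$t2_bg + im$t2_increment
  if (im$noise_sd > 0) {
    set.seed(spec$seed)
    t1 <- t1 + array(stats::rnorm(prod(d), sd = im$noise_sd), dim = d)
    t2 <- t2 + array(stats::rnorm(prod(d), sd = im$noise_sd), dim = d)
  }
  list(
    pair = structural_pair(t1, t2, voxel_size = vs),
    atlas = atlas,
    truth_mask = truth,
    tube_table = if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(tube = integer(), region = character(),
                     hemisphere = character(), radius = numeric(),
                     length = numeric(), analytic_volume = numeric(),
                     voxel_count = integer())
  )
}
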