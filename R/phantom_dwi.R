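#' Diffusion gradient scheme
#'
#' Builds a single-shell diffusion scheme: `n_b0` reference volumes at b = 0
#' followed by `n_dirs` unit gradient directions at `bvalue`. Directions are
#' placed deterministically on a spherical Fibonacci lattice, which gives a
#' near-uniform angular coverage suitable for tensor fitting. The default
#' mirrors a common clinical protocol: 64 directions at b = 1000 s/mm^2 plus
#' five b = 0 images.
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param n_b0 Number of b = 0 reference volumes.
#' @param bvalue Diffusion weighting in s/mm^2.
#' @return A list with `bvalues` (length `n_b0 + n_dirs`) and `bvecs`
#'   (3 x n matrix of unit columns; zero columns for b = 0 volumes).
#' @export
#' @examples
#' sch <- dwi_scheme(n_dirs = 12)
#' colSums(sch$bvecs^2)[sch$bvalues > 0]
dwi_scheme <- function(n_dirs = 64L, n_b0 = 5L, bvalue = 1000) {
  assert_that(n_dirs >= 6, "at least 6 diffusion directions are required")
  assert_that(n_b0 >= 1, "at least one b = 0 volume is required")
  i <- seq_len(n_dirs) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * i
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  list(
    bvalues = c(rep(0, n_b0), rep(bvalue, n_dirs)),
    bvecs = cbind(matrix(0, 3, n_b0), dirs)
  )
}

#' Specify a diffusion-weighted phantom
#'
#' Describes a rectilinear DWI phantom made of labelled regions, each with its
#' own diffusion tensor (three eigenvalues plus a principal axis). Three
#' ready-made layouts cover the DTI-ALPS use cases:
#'
#' * `"alps"` — an isotropic background containing a projection-fiber block
#'   (principal axis z) and an association-fiber block (principal axis y),
#'   the geometry of the periventricular ALPS ROI neighbourhood where
#'   perivascular spaces run along x, perpendicular to both tracts. The
#'   `pvs_dxx` argument optionally elevates the x-axis diffusivity of both
#'   blocks, emulating perivascular water flux (the ALPS signal itself).
#' * `"alps_oracle"` — both blocks carry their principal axis along x, so the
#'   full pipeline must return exactly the ratio of the parallel to the
#'   perpendicular eigenvalue; used as an arithmetic oracle.
#' * `"isotropic"` — a uniform isotropic volume (ALPS index must be 1).
#'
#' Custom geometries are given via `regions`, a list of
#' `list(label =, bounds = 3x2 index range matrix, eigenvalues =, axis =)`;
#' later regions overwrite earlier ones.
#'
#' @param grid_shape Integer vector of voxels per axis.
#' @param voxel_size Numeric vector, mm per axis.
#' @param layout One of `"alps"`, `"alps_oracle"`, `"isotropic"`, `"custom"`.
#' @param eigenvalues Fiber-block eigenvalues in mm^2/s, sorted descending;
#'   defaults to canonical white-matter values (1.7, 0.3, 0.3) x 1e-3.
#' @param iso_diffusivity Background isotropic diffusivity in mm^2/s.
#' @param pvs_dxx Optional x-axis diffusivity (mm^2/s) replacing the
#'   perpendicular eigenvalue along x in the `"alps"` layout fiber blocks.
#' @param regions Custom region list (see Details); required for
#'   `layout = "custom"`.
#' @param scheme Gradient scheme from [dwi_scheme()].
#' @param s0 Baseline (b = 0) signal intensity.
#' @param snr Signal-to-noise ratio referenced to `s0`; `Inf` for noiseless.
#' @param seed Integer seed for the noise generator.
#' @return A `dwi_phantom_spec` object.
#' @seealso [make_dwi_phantom()]
#' @export
dwi_phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                             voxel_size = c(1, 1, 1),
                             layout = c("alps", "alps_oracle", "isotropic", "custom"),
                             eigenvalues = c(1.7e-3, 3e-4, 3e-4),
                             iso_diffusivity = 1e-3,
                             pvs_dxx = NULL,
                             regions = NULL,
                             scheme = dwi_scheme(),
                             s0 = 1000,
                             snr = Inf,
                             seed = 1L) {
  layout <- match.arg(layout)
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 1),
              "`grid_shape` must be three positive integers")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "`voxel_size` must be three positive lengths in mm")
  assert_that(all(eigenvalues >= 0), "eigenvalues must be non-negative")
  assert_that(sum(scheme$bvalues == 0) >= 1, "scheme needs at least one b = 0 volume")
  nz <- scheme$bvalues > 0
  norms <- sqrt(colSums(scheme$bvecs[, nz, drop = FALSE]^2))
  assert_that(all(abs(norms - 1) <= 1e-8),
              "every non-zero-b gradient direction must have unit norm")
  assert_that(is_scalar_number(s0) && s0 > 0, "`s0` must be positive")
  assert_that((is.numeric(snr) && length(snr) == 1 && snr > 0),
              "`snr` must be a positive number or Inf")

  if (layout == "custom") {
    assert_that(!is.null(regions), "`layout = \"custom\"` requires `regions`")
  } else {
    regions <- build_alps_layout(grid_shape, layout, eigenvalues,
                                 iso_diffusivity, pvs_dxx)
  }
  for (rg in regions) {
    assert_that(all(rg$eigenvalues >= 0),
                sprintf("region '%s' has a negative eigenvalue", rg$label))
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
         layout = layout, regions = regions, scheme = scheme,
         s0 = s0, snr = snr, seed = normalize_seed(seed)),
    class = "dwi_phantom_spec"
  )
}

# Region layout shared by the ready-made DWI phantoms: two fiber blocks in an
# isotropic background, split along x with a background margin.
build_alps_layout <- function(grid_shape, layout, eigenvalues,
                              iso_diffusivity, pvs_dxx) {
  iso <- list(
    label = "background",
    bounds = cbind(rep(1L, 3), grid_shape),
    eigenvalues = rep(iso_diffusivity, 3),
    axis = c(1, 0, 0)
  )
  if (layout == "isotropic") return(list(iso))
  nx <- grid_shape[1]
  lo <- pmax(1L, round(grid_shape * 0.2))
  hi <- pmin(grid_shape, round(grid_shape * 0.8))
  xm <- max(lo[1] + 1L, floor(nx / 2))
  proj_bounds <- rbind(c(lo[1], xm), c(lo[2], hi[2]), c(lo[3], hi[3]))
  assoc_bounds <- rbind(c(xm + 1L, hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3]))
  if (layout == "alps_oracle") {
    proj_axis <- assoc_axis <- c(1, 0, 0)
    ev_proj <- ev_assoc <- eigenvalues
  } else {
    proj_axis <- c(0, 0, 1)
    assoc_axis <- c(0, 1, 0)
    ev_proj <- ev_assoc <- eigenvalues
    if (!is.null(pvs_dxx)) {
      # elevated diffusivity along the perivascular x direction: supply the
      # full tensor via eigenvalues in the region frame (axis first)
      ev_proj <- c(eigenvalues[1], pvs_dxx, eigenvalues[3])
      ev_assoc <- c(eigenvalues[1], pvs_dxx, eigenvalues[3])
    }
  }
  list(
    iso,
    list(label = "projection", bounds = proj_bounds,
         eigenvalues = ev_proj, axis = proj_axis),
    list(label = "association", bounds = assoc_bounds,
         eigenvalues = ev_assoc, axis = assoc_axis)
  )
}

#' ALPS ROI coordinates for a phantom layout
#'
#' Returns the world-mm centers of the projection- and association-fiber ROIs
#' for a phantom built by [dwi_phantom_spec()] (block centroids), in the tidy
#' layout consumed by [compute_alps()].
#'
#' @param spec A `dwi_phantom_spec`.
#' @param diameter ROI diameter in mm (the standard protocol uses 5 mm
#'   spheres).
#' @return A tibble with columns `fiber_type`, `hemisphere`, `x`, `y`, `z`,
#'   `diameter`.
#' @export
phantom_roi_table <- function(spec, diameter = 5) {
  assert_that(inherits(spec, "dwi_phantom_spec"), "`spec` must be a dwi_phantom_spec")
  regs <- spec$regions
  labs <- vapply(regs, `[[`, "", "label")
  assert_that(all(c("projection", "association") %in% labs),
              "layout has no fiber blocks; use an 'alps' layout")
  center_of <- function(rg) {
    mid <- (rg$bounds[, 1] + rg$bounds[, 2]) / 2
    (mid - 1) * spec$voxel_size
  }
  pc <- center_of(regs[[which(labs == "projection")]])
  ac <- center_of(regs[[which(labs == "association")]])
  tibble::tibble(
    fiber_type = c("projection", "association"),
    hemisphere = "left",
    x = c(pc[1], ac[1]), y = c(pc[2], ac[2]), z = c(pc[3], ac[3]),
    diameter = diameter
  )
}

#' Generate a diffusion-weighted phantom
#'
#' Simulates the DWI signal of every voxel from its region's diffusion tensor
#' with the mono-exponential forward model S = S0 exp(-b g' D g). With finite
#' `snr`, Rician noise of sigma = S0/snr is applied channel-wise (Gaussian
#' noise added in quadrature to the complex signal before taking magnitude),
#' matching the statistics of magnitude MR data.
#'
#' @param spec A [dwi_phantom_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{dwi}{a [diffusion_volume()] holding the simulated 4D signal.}
#'     \item{truth}{a `tensor_field` holding the exact generating tensors.}
#'     \item{labels}{integer 3D array of region indices into `spec$regions`.}
#'   }
#' @export
#' @examples
#' ph <- make_dwi_phantom(dwi_phantom_spec(grid_shape = c(8, 8, 8),
#'                                         layout = "isotropic"))
#' dim(ph$dwi$signal)
make_dwi_phantom <- function(spec) {
  assert_that(inherits(spec, "dwi_phantom_spec"), "`spec` must be a dwi_phantom_spec")
  d <- spec$grid_shape
  nvol <- length(spec$scheme$bvalues)
  labels <- array(0L, dim = d)
  for (i in seq_along(spec$regions)) {
    b <- spec$regions[[i]]$bounds
    labels[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]] <- i
  }
  assert_that(all(labels > 0), "region layout leaves unlabelled voxels")

  # per-region signal profile over volumes, then broadcast to voxels
  profiles <- matrix(0, length(spec$regions), nvol)
  tensors6 <- matrix(0, length(spec$regions), 6)
  b <- spec$scheme$bvalues
  g <- spec$scheme$bvecs
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    D <- tensor_from_eigen(rg$eigenvalues, rg$axis)
    tensors6[i, ] <- tensor_to_vec6(D)
    adc <- colSums(g * (D %*% g))
    profiles[i, ] <- spec$s0 * exp(-b * adc)
  }
  signal <- array(0, dim = c(d, nvol))
  lab_vec <- as.vector(labels)
  nv <- prod(d)
  for (v in seq_len(nvol)) {
    signal[, , , v] <- array(profiles[lab_vec, v], dim = d)
  }
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    set.seed(spec$seed)
    e1 <- array(stats::rnorm(nv * nvol, sd = sigma), dim = c(d, nvol))
    e2 <- array(stats::rnorm(nv * nvol, sd = sigma), dim = c(d, nvol))
    signal <- sqrt((signal + e1)^2 + e2^2)
  }
  dwi <- diffusion_volume(signal, spec$scheme$bvalues, spec$scheme$bvecs,
                          voxel_size = spec$voxel_size)
  truth <- tensor_field_from_vec6(tensors6[lab_vec, , drop = FALSE], d,
                                  spec$voxel_size)
  list(dwi = dwi, truth = truth, labels = labels)
}

#' Construct a diffusion volume
#'
#' Container for a 4D diffusion-weighted acquisition: the signal array, per
#' volume b-values and unit gradient directions, and the voxel geometry. At
#' least one b = 0 volume and six non-collinear weighted directions are
#' required so a tensor is identifiable.
#'
#' @param signal 4D numeric array (x, y, z, volume), non-negative.
#' @param bvalues Numeric vector, s/mm^2, one per volume.
#' @param bvecs 3 x n matrix of gradient directions (unit columns at b > 0).
#' @param voxel_size Voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity with the first voxel center at the origin (RAS).
#' @return A `diffusion_volume` object.
#' @export
diffusion_volume <- function(signal, bvalues, bvecs, voxel_size = c(1, 1, 1),
                             affine = NULL) {
  assert_that(length(dim(signal)) == 4, "`signal` must be a 4D array")
  assert_that(all(is.finite(signal)) && min(signal) >= 0,
              "`signal` must be finite and non-negative")
  nvol <- dim(signal)[4]
  assert_that(length(bvalues) == nvol && ncol(bvecs) == nvol,
              "`bvalues`/`bvecs` must match the number of volumes")
  assert_that(sum(bvalues == 0) >= 1, "at least one b = 0 volume is required")
  nz <- bvalues > 0
  norms <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
  assert_that(all(abs(norms - 1) <= 1e-8),
              "gradient directions at b > 0 must be unit vectors")
  dirs <- unique(round(t(bvecs[, nz, drop = FALSE]), 6))
  assert_that(nrow(dirs) >= 6, "at least 6 unique diffusion directions required")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(signal = signal, bvalues = as.numeric(bvalues), bvecs = bvecs,
         voxel_size = as.numeric(voxel_size), affine = affine),
    class = "diffusion_volume"
  )
}

#' @export
print.diffusion_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<diffusion_volume> %dx%dx%d grid, %d volumes (%d b=0), b max %g s/mm^2\n",
              d[1], d[2], d[3], d[4], sum(x$bvalues == 0), max(x$bvalues)))
  invisible(x)
}
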