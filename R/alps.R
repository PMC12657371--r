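#' Voxels inside a spherical ROI
#'
#' Selects every voxel whose center lies within `diameter/2` (world mm) of the
#' ROI center, matching the standard DTI-ALPS protocol of 5-mm diameter
#' spherical ROIs placed on the color-FA map.
#'
#' @param roi A list or one-row data frame with `x`, `y`, `z` (center, world
#'   mm) and `diameter` (mm, default 5).
#' @param field A `tensor_field` (supplies the grid and voxel size).
#' @return Integer vector of linear voxel indices (non-empty).
#' @export
sphere_roi <- function(roi, field) {
  assert_that(inherits(field, "tensor_field"), "`field` must be a tensor_field")
  center <- as.numeric(c(roi$x, roi$y, roi$z))
  diameter <- as.numeric(roi$diameter %||% 5)
  assert_that(length(center) == 3 && all(is.finite(center)),
              "ROI center must be three finite coordinates")
  assert_that(diameter > 0, "ROI diameter must be positive")
  d <- dim(field$fa)
  ax <- voxel_centers(d, field$voxel_size)
  for (k in 1:3) {
    assert_that(center[k] >= min(ax[[k]]) - field$voxel_size[k] / 2 &&
                center[k] <= max(ax[[k]]) + field$voxel_size[k] / 2,
                "ROI center lies outside the volume")
  }
  r2 <- (diameter / 2)^2
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
  idx <- which(inside)
  assert_that(length(idx) > 0, "spherical ROI contains no voxel centers")
  idx
}

#' ROI-mean diagonal diffusivities
#'
#' Arithmetic mean of the tensor's diagonal elements Dxx, Dyy, Dzz over an ROI,
#' taken in the native image axes (the acquisition is assumed axis-aligned, as
#' when reading diffusivities off a color-FA map; no tensor reorientation).
#' Flagged (zero-tensor) voxels are excluded.
#'
#' @param field A `tensor_field`.
#' @param voxels Linear voxel indices, e.g. from [sphere_roi()].
#' @return Named numeric vector `c(dxx =, dyy =, dzz =)` in mm^2/s.
#' @export
extract_diffusivities <- function(field, voxels) {
  assert_that(inherits(field, "tensor_field"), "`field` must be a tensor_field")
  assert_that(length(voxels) > 0, "ROI is empty")
  keep <- voxels[!field$flagged[voxels]]
  assert_that(length(keep) > 0, "all ROI voxels are flagged; no usable tensors")
  nvox <- prod(dim(field$fa))
  tens <- matrix(field$tensor, nvox, 6)
  c(dxx = mean(tens[keep, 1]), dyy = mean(tens[keep, 2]),
    dzz = mean(tens[keep, 3]))
}

#' DTI-ALPS index
#'
#' The ALPS index is the ratio of perivascular-direction (x-axis) diffusivity
#' to the fiber-perpendicular diffusivities measured in two ROIs at the level
#' of the lateral-ventricle body, where perivascular spaces run along x,
#' perpendicular to the projection fibers (z) and association fibers (y):
#'
#' \deqn{ALPS = mean(Dxx_{proj}, Dxx_{assoc}) / mean(Dyy_{proj}, Dzz_{assoc})}
#'
#' An index near 1 indicates no preferential perivascular diffusion; larger
#' values indicate greater water mobility along the perivascular axis, read as
#' a proxy of glymphatic function.
#'
#' @param dxx_proj,dxx_assoc x-axis diffusivities (mm^2/s) of the projection
#'   and association ROIs.
#' @param dyy_proj y-axis diffusivity of the projection ROI.
#' @param dzz_assoc z-axis diffusivity of the association ROI.
#' @param hemisphere Label carried into the result (default "left"; unilateral
#'   left-hemisphere assessment is the common protocol).
#' @return An `alps_result` with the four inputs and `alps_index`.
#' @export
#' @examples
#' alps_index(1.6e-3, 1.6e-3, 1.0e-3, 1.2e-3)$alps_index  # 1.4545...
alps_index <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc,
                       hemisphere = "left") {
  vals <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  assert_that(length(vals) == 4 && all(is.finite(vals)),
              "all four diffusivities must be finite scalars")
  denom <- mean(c(dyy_proj, dzz_assoc))
  assert_that(denom > 0,
              sprintf("non-positive denominator mean(Dyy_proj, Dzz_assoc) = %g; check ROI placement and tensor signs", denom))
  structure(
    list(dxx_proj = dxx_proj, dxx_assoc = dxx_assoc,
         dyy_proj = dyy_proj, dzz_assoc = dzz_assoc,
         alps_index = mean(c(dxx_proj, dxx_assoc)) / denom,
         hemisphere = hemisphere),
    class = "alps_result"
  )
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> %s hemisphere: ALPS = %.4f\n", x$hemisphere, x$alps_index))
  cat(sprintf("  Dxx proj/assoc: %.3e / %.3e  Dyy proj: %.3e  Dzz assoc: %.3e (mm^2/s)\n",
              x$dxx_proj, x$dxx_assoc, x$dyy_proj, x$dzz_assoc))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy alps_result
#' @export
tidy.alps_result <- function(x, ...) {
  tibble::tibble(
    hemisphere = x$hemisphere,
    dxx_proj = x$dxx_proj, dxx_assoc = x$dxx_assoc,
    dyy_proj = x$dyy_proj, dzz_assoc = x$dzz_assoc,
    alps_index = x$alps_index
  )
}

#' ALPS index from a tensor field and an ROI table
#'
#' Runs the full ROI stage: for each hemisphere in `roi_table` it selects the
#' projection- and association-fiber spherical ROIs, averages the diagonal
#' diffusivities, and forms the ALPS ratio.
#'
#' @param field A `tensor_field` from [fit_tensors()].
#' @param roi_table Data frame with columns `fiber_type`
#'   ("projection"/"association"), `hemisphere`, `x`, `y`, `z` (mm) and
#'   `diameter` (mm); see [phantom_roi_table()] and [read_roi_table()].
#' @return A tibble, one row per hemisphere, with the four ROI diffusivities
#'   and `alps_index`.
#' @export
compute_alps <- function(field, roi_table) {
  assert_that(is.data.frame(roi_table) && nrow(roi_table) >= 2,
              "`roi_table` needs projection and association rows")
  needed <- c("fiber_type", "hemisphere", "x", "y", "z")
  assert_that(all(needed %in% names(roi_table)),
              "`roi_table` must have fiber_type, hemisphere, x, y, z columns")
  roi_table$diameter <- roi_table$diameter %||% 5
  purrr::map_dfr(split(roi_table, roi_table$hemisphere), function(tab) {
    pr <- tab[tab$fiber_type == "projection", , drop = FALSE]
    as <- tab[tab$fiber_type == "association", , drop = FALSE]
    assert_that(nrow(pr) == 1 && nrow(as) == 1,
                "each hemisphere needs exactly one projection and one association ROI")
    dp <- extract_diffusivities(field, sphere_roi(pr, field))
    da <- extract_diffusivities(field, sphere_roi(as, field))
    tidy(alps_index(dp[["dxx"]], da[["dxx"]], dp[["dyy"]], da[["dzz"]],
                    hemisphere = tab$hemisphere[1]))
  })
}
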