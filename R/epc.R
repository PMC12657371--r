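#' Enhanced PVS contrast (EPC) image
#'
#' Divides the (filtered) T1-weighted volume by the (filtered) T2-weighted
#' volume. Because perivascular spaces are dark on T1w and bright on T2w, the
#' ratio amplifies their contrast: PVS appear as dark tubes on the EPC image.
#' Voxels where T2w falls below `eps` are excluded from the validity mask and
#' the denominator is floored at `eps`, so no infinities are produced.
#'
#' @param pair A [structural_pair()]; filter both channels first (see
#'   [nlm_filter()]), since the ratio is intended to be formed from
#'   noise-suppressed images.
#' @param eps Small positive denominator floor.
#' @return An `epc_volume`: `epc` array, logical `mask` of valid voxels, and
#'   voxel geometry.
#' @export
compute_epc <- function(pair, eps = 1e-6) {
  assert_that(inherits(pair, "structural_pair"), "`pair` must be a structural_pair")
  assert_that(is_scalar_number(eps) && eps > 0, "`eps` must be a small positive number")
  mask <- pair$t2w >= eps
  epc <- pair$t1w / pmax(pair$t2w, eps)
  epc[!mask] <- 0
  structure(
    list(epc = epc, mask = mask, voxel_size = pair$voxel_size,
         affine = pair$affine),
    class = "epc_volume"
  )
}

#' @export
print.epc_volume <- function(x, ...) {
  cat(sprintf("<epc_volume> %s grid, %d valid voxels, range [%.3f, %.3f]\n",
              paste(dim(x$epc), collapse = "x"), sum(x$mask),
              min(x$epc[x$mask]), max(x$epc[x$mask])))
  invisible(x)
}
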