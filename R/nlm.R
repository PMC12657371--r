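#' Adaptive non-local means filtering
#'
#' Denoises a 3D volume by averaging voxels with similar local patches: the
#' weight between a voxel and a candidate at offset o decays with the
#' patch-mean squared intensity difference, after subtracting the expected
#' noise contribution 2 sigma^2 (so identical patches under noise still get
#' full weight). With `h = "auto"` the decay constant is set to a robust
#' noise-SD estimate obtained from pseudo-residuals against the 6-neighbour
#' mean (median absolute deviation of the high-frequency residual).
#'
#' The output is a convex combination of input intensities, so it always stays
#' within the input range. `h = 0` disables smoothing and returns the input.
#'
#' @param volume 3D numeric array, all finite.
#' @param patch_radius Patch half-width in voxels (patch edge 2r+1).
#' @param search_radius Search-window half-width in voxels.
#' @param h Smoothing strength (intensity units), or `"auto"`.
#' @return Filtered array of the same shape, with the noise-SD estimate in
#'   attribute `"sigma"`.
#' @export
nlm_filter <- function(volume, patch_radius = 1L, search_radius = 2L, h = "auto") {
  assert_that(length(dim(volume)) == 3, "`volume` must be a 3D array")
  assert_that(all(is.finite(volume)), "`volume` contains non-finite voxels")
  sigma <- estimate_noise_sd(volume)
  if (identical(h, "auto")) {
    h <- sigma
  } else {
    assert_that(is_scalar_number(h) && h >= 0, "`h` must be a non-negative number")
  }
  if (h == 0) {
    return(structure(volume, sigma = sigma))
  }
  box <- rep(1, 2 * patch_radius + 1) / (2 * patch_radius + 1)
  patch_mean <- function(x) {
    for (ax in 1:3) x <- conv_axis(x, box, ax)
    x
  }
  offs <- as.matrix(expand.grid(dx = -search_radius:search_radius,
                                dy = -search_radius:search_radius,
                                dz = -search_radius:search_radius))
  num <- array(0, dim = dim(volume))
  den <- array(0, dim = dim(volume))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    shifted <- volume
    for (ax in 1:3) if (o[ax] != 0) shifted <- shift_array(shifted, ax, o[ax])
    d2 <- patch_mean((volume - shifted)^2)
    w <- exp(-pmax(d2 - 2 * sigma^2, 0) / h^2)
    num <- num + w * shifted
    den <- den + w
  }
  structure(num / den, sigma = sigma)
}

# Robust noise SD via pseudo-residuals against the 6-neighbour mean:
# eps = sqrt(6/7) (I - mean of face neighbours) has SD sigma under iid noise.
estimate_noise_sd <- function(volume) {
  nb <- array(0, dim = dim(volume))
  for (ax in 1:3) {
    nb <- nb + shift_array(volume, ax, 1L) + shift_array(volume, ax, -1L)
  }
  eps <- sqrt(6 / 7) * (volume - nb / 6)
  stats::mad(as.vector(eps), center = 0)
}
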