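# Internal array and validation helpers shared across the imaging modules.

abort_glymph <- function(msg, class = "glymphkit_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_glymph(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @keywords internal
#' @noRd
normalize_seed <- function(seed) {
  assert_that(is_scalar_number(seed) && seed == floor(seed),
              "`seed` must be a single integer")
  as.integer(seed %% .Machine$integer.max)
}

# Shift a 3D array by `k` voxels along `axis`; out-of-range voxels take the
# edge value (replicate padding), or `fill` when given.
shift_array <- function(x, axis, k, fill = NULL) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - k
  if (is.null(fill)) {
    src <- pmin(pmax(src, 1L), d[axis])
    idx[[axis]] <- src
    return(do.call(`[`, c(list(x), idx)))
  }
  keep <- src >= 1L & src <= d[axis]
  out <- array(fill, dim = d)
  idx_out <- idx
  idx_out[[axis]] <- which(keep)
  idx[[axis]] <- src[keep]
  if (any(keep)) {
    out_sub <- do.call(`[`, c(list(x), idx))
    out <- do.call(`[<-`, c(list(out), idx_out, list(out_sub)))
  }
  out
}

# Separable 1D convolution along one axis with replicate padding.
conv_axis <- function(x, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(x))
  for (j in seq_along(kernel)) {
    if (kernel[j] == 0) next
    out <- out + kernel[j] * shift_array(x, axis, j - r - 1L)
  }
  out
}

gaussian_kernel_1d <- function(sigma, order = 0L) {
  if (sigma <= 0) {
    if (order == 0L) return(1)
    # Central-difference fall-backs at zero scale
    if (order == 1L) return(c(-0.5, 0, 0.5))
    return(c(1, -2, 1))
  }
  r <- max(1L, ceiling(3 * sigma))
  u <- (-r):r
  g <- exp(-u^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -u / sigma^2 * g
    # enforce exact response to a linear ramp
    k <- k / sum(-u * k) * 1
    return(k)
  }
  k <- (u^2 / sigma^2 - 1) / sigma^2 * g
  k - mean(k)
}

# Smooth a 3D volume with an isotropic-in-mm Gaussian given per-axis voxel
# sizes (sigma in mm -> per-axis sigma in voxels).
gaussian_smooth_3d <- function(x, sigma_mm, voxel_size) {
  for (ax in 1:3) {
    s <- sigma_mm / voxel_size[ax]
    if (s > 0) x <- conv_axis(x, gaussian_kernel_1d(s), ax)
  }
  x
}

# World (mm) coordinates of every voxel center along each axis, for a simple
# axis-aligned affine with origin at the first voxel center.
voxel_centers <- function(dim3, voxel_size) {
  lapply(1:3, function(ax) (seq_len(dim3[ax]) - 1) * voxel_size[ax])
}

as_unit <- function(v) {
  n <- sqrt(sum(v^2))
  assert_that(n > 0, "direction vector must be non-zero")
  v / n
}

# Orthonormal basis with `axis` as the first column; deterministic completion.
basis_from_axis <- function(axis) {
  e1 <- as_unit(axis)
  helper <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- helper - sum(helper * e1) * e1
  e2 <- as_unit(e2)
  e3 <- c(
    e1[2] * e2[3] - e1[3] * e2[2],
    e1[3] * e2[1] - e1[1] * e2[3],
    e1[1] * e2[2] - e1[2] * e2[1]
  )
  cbind(e1, e2, e3, deparse.level = 0)
}

# Symmetric tensor from eigenvalues and principal axis: lambda1 along `axis`,
# remaining eigenvalues on the deterministic perpendicular completion.
tensor_from_eigen <- function(eigenvalues, axis) {
  R <- basis_from_axis(axis)
  R %*% diag(eigenvalues) %*% t(R)
}

# Pack/unpack the 6 unique components in (xx, yy, zz, xy, xz, yz) order.
tensor_to_vec6 <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

vec6_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}
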