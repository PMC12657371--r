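#' Frangi filter parameters
#'
#' Tunables of the multi-scale Hessian vesselness filter. `alpha` penalises
#' plate-like structure (ratio |lambda2|/|lambda3|), `beta` penalises blob-like
#' structure (|lambda1|/sqrt(|lambda2 lambda3|)), and `c` weights second-order
#' structureness (the Frobenius norm of the Hessian); with `c = "adaptive"` it
#' is set per scale to half the maximum Frobenius norm, which adapts the
#' filter to the image's contrast. Scales are Gaussian sigmas in mm and should
#' bracket the tube radii of interest; the defaults span common perivascular
#' space calibers. `polarity = "dark"` targets tubes darker than background
#' (the EPC appearance of PVS).
#'
#' @param scales Gaussian scales in mm.
#' @param alpha,beta Positive discrimination weights (canonical 0.5).
#' @param c `"adaptive"` or a positive number.
#' @param polarity `"dark"` or `"bright"`.
#' @return A `frangi_params` list.
#' @export
frangi_params <- function(scales = c(0.5, 1, 1.5, 2), alpha = 0.5, beta = 0.5,
                          c = "adaptive", polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  assert_that(length(scales) >= 1 && all(scales > 0), "`scales` must be positive")
  assert_that(alpha > 0 && beta > 0, "`alpha` and `beta` must be positive")
  if (!identical(c, "adaptive")) {
    assert_that(is_scalar_number(c) && c > 0, "`c` must be \"adaptive\" or positive")
  }
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 polarity = polarity),
            class = "frangi_params")
}

# Scale-normalized Hessian of a 3D volume at Gaussian scale sigma (mm):
# Gaussian-derivative convolutions per axis (sigma converted to voxels),
# derivatives expressed per mm, whole Hessian multiplied by sigma^2.
hessian_3d <- function(vol, sigma_mm, voxel_size) {
  deriv <- function(x, orders) {
    for (ax in 1:3) {
      s <- sigma_mm / voxel_size[ax]
      k <- gaussian_kernel_1d(s, order = orders[ax])
      x <- conv_axis(x, k, ax)
      if (orders[ax] > 0) x <- x / voxel_size[ax]^orders[ax]
    }
    x
  }
  ords <- list(xx = c(2, 0, 0), yy = c(0, 2, 0), zz = c(0, 0, 2),
               xy = c(1, 1, 0), xz = c(1, 0, 1), yz = c(0, 1, 1))
  lapply(ords, function(o) sigma_mm^2 * deriv(vol, o))
}

# Eigenvalues of a field of symmetric 3x3 matrices (closed-form trigonometric
# solution), returned sorted by increasing absolute value as an n x 3 matrix.
symm3_eigen_absorted <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p; b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  E <- cbind(e1, e2, e3)
  ab <- abs(E)
  n <- nrow(E)
  i_hi <- max.col(ab, ties.method = "first")
  i_lo <- max.col(-ab, ties.method = "last")
  same <- i_hi == i_lo
  i_lo[same] <- 1L; i_hi[same] <- 3L
  i_mid <- 6L - i_hi - i_lo
  cbind(E[cbind(seq_len(n), i_lo)], E[cbind(seq_len(n), i_mid)],
        E[cbind(seq_len(n), i_hi)])
}

#' Multi-scale Frangi vesselness
#'
#' Computes, per voxel and Gaussian scale, the eigenvalues of the
#' scale-normalized Hessian sorted by absolute value, gates on tube polarity
#' (dark tubes require the two dominant eigenvalues to be positive), and forms
#' Frangi's tubularity response
#' \deqn{(1 - e^{-R_A^2/2\alpha^2})\, e^{-R_B^2/2\beta^2}\, (1 - e^{-S^2/2c^2})}
#' with \eqn{R_A = |\lambda_2|/|\lambda_3|},
#' \eqn{R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}} and
#' \eqn{S = \sqrt{\sum \lambda_i^2}}. The map is the maximum over scales and is
#' bounded in \[0, 1\]; uniform volumes score exactly 0.
#'
#' @param epc An `epc_volume` (from [compute_epc()]), or a plain 3D array.
#' @param params A [frangi_params()].
#' @param voxel_size Required only when `epc` is a plain array.
#' @return A `vesselness_map` with the response array `v` in \[0, 1\].
#' @export
frangi_vesselness <- function(epc, params = frangi_params(), voxel_size = NULL) {
  assert_that(inherits(params, "frangi_params"), "`params` must be frangi_params")
  if (inherits(epc, "epc_volume")) {
    vol <- epc$epc
    voxel_size <- epc$voxel_size
  } else {
    assert_that(length(dim(epc)) == 3, "`epc` must be 3D")
    assert_that(!is.null(voxel_size), "`voxel_size` required for plain arrays")
    vol <- epc
  }
  assert_that(all(is.finite(vol)), "EPC volume contains non-finite voxels")
  d <- dim(vol)
  v <- array(0, dim = d)
  sgn <- if (params$polarity == "dark") 1 else -1
  for (sigma in params$scales) {
    H <- hessian_3d(vol, sigma, voxel_size)
    lam <- symm3_eigen_absorted(H$xx, H$yy, H$zz, H$xy, H$xz, H$yz)
    l1 <- lam[, 1]; l2 <- lam[, 2]; l3 <- lam[, 3]
    gate <- (sgn * l2 > 0) & (sgn * l3 > 0)
    S2 <- l1^2 + l2^2 + l3^2
    # floating-point floor: a flat volume has no second-order structure, so
    # the adaptive structureness weight must not rescale to numerical noise
    if (sqrt(max(S2)) <= 1e-8 * max(abs(vol), 1)) next
    cc <- if (identical(params$c, "adaptive")) 0.5 * sqrt(max(S2)) else params$c
    resp <- numeric(length(l1))
    ok <- which(gate & abs(l3) > 0 & cc > 0)
    if (length(ok)) {
      Ra2 <- (l2[ok] / l3[ok])^2
      Rb2 <- l1[ok]^2 / abs(l2[ok] * l3[ok])
      resp[ok] <- (1 - exp(-Ra2 / (2 * params$alpha^2))) *
        exp(-Rb2 / (2 * params$beta^2)) *
        (1 - exp(-S2[ok] / (2 * cc^2)))
    }
    v <- pmax(v, array(resp, dim = d))
  }
  structure(
    list(v = pmin(pmax(v, 0), 1), voxel_size = voxel_size, params = params),
    class = "vesselness_map"
  )
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat(sprintf("<vesselness_map> %s grid, scales {%s} mm, max response %.3f\n",
              paste(dim(x$v), collapse = "x"),
              paste(x$params$scales, collapse = ", "), max(x$v)))
  invisible(x)
}
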