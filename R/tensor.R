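#' Fit diffusion tensors voxel-wise
#'
#' Estimates a symmetric diffusion tensor in every voxel from the log-linear
#' model ln(S/S0) = -b g' D g, where S0 is the mean of the b = 0 volumes.
#' The default weighted fit performs an ordinary least-squares pass and then
#' reweights by the squared predicted signal, the standard heteroscedasticity
#' correction for log-transformed MR magnitude data; `method = "ols"` skips
#' the reweighting. Voxels with non-positive S0 or diffusion-weighted signal
#' are assigned a zero tensor and flagged; downstream ROI statistics exclude
#' them.
#'
#' @param dwi A [diffusion_volume()].
#' @param method `"wls"` (weighted log-linear, default) or `"ols"`.
#' @return A `tensor_field`: per-voxel tensor components
#'   (xx, yy, zz, xy, xz, yz in mm^2/s), eigenvalues sorted descending,
#'   principal eigenvector, fractional anisotropy, color-FA
#'   (|principal eigenvector| scaled by FA) and a `flagged` mask. Negative
#'   eigenvalues are clamped to zero for FA/color-FA only; the raw tensor is
#'   retained.
#' @export
#' @examples
#' ph <- make_dwi_phantom(dwi_phantom_spec(grid_shape = c(6, 6, 6),
#'                                         layout = "isotropic"))
#' tf <- fit_tensors(ph$dwi)
#' max(abs(tf$fa))  # isotropic: FA = 0
fit_tensors <- function(dwi, method = c("wls", "ols")) {
  assert_that(inherits(dwi, "diffusion_volume"), "`dwi` must be a diffusion_volume")
  method <- match.arg(method)
  d <- dim(dwi$signal)[1:3]
  nvox <- prod(d)
  b0_idx <- which(dwi$bvalues == 0)
  dw_idx <- which(dwi$bvalues > 0)
  assert_that(length(dw_idx) >= 6, "need >= 6 diffusion-weighted volumes")

  sig <- matrix(dwi$signal, nvox, length(dwi$bvalues))
  s0 <- rowMeans(sig[, b0_idx, drop = FALSE])
  sw <- sig[, dw_idx, drop = FALSE]

  flagged <- s0 <= 0 | apply(sw <= 0, 1, any)
  ok <- which(!flagged)

  g <- dwi$bvecs[, dw_idx, drop = FALSE]
  bb <- dwi$bvalues[dw_idx]
  A <- -bb * cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
                   2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ])

  vec6 <- matrix(0, nvox, 6)
  if (length(ok)) {
    Y <- log(sw[ok, , drop = FALSE] / s0[ok])     # nok x ndir
    D_ols <- t(solve(crossprod(A), crossprod(A, t(Y))))
    if (method == "ols") {
      vec6[ok, ] <- D_ols
    } else {
      pred <- tcrossprod(D_ols, A)                # predicted log-signal ratio
      W <- exp(2 * pred)                          # squared predicted signal (rel.)
      for (j in seq_along(ok)) {
        w <- W[j, ]
        Aw <- A * w
        vec6[ok[j], ] <- solve(crossprod(A, Aw), crossprod(Aw, Y[j, ]))
      }
    }
  }
  tensor_field_from_vec6(vec6, d, dwi$voxel_size, flagged = flagged,
                         affine = dwi$affine)
}

# Build a full tensor_field (eigensystem, FA, color-FA) from an nvox x 6
# component matrix. Voxels sharing identical components are decomposed once.
tensor_field_from_vec6 <- function(vec6, dim3, voxel_size,
                                   flagged = rep(FALSE, nrow(vec6)),
                                   affine = NULL) {
  nvox <- nrow(vec6)
  key <- do.call(paste, c(as.data.frame(vec6), list(sep = ",")))
  uidx <- which(!duplicated(key))
  map <- match(key, key[uidx])

  nu <- length(uidx)
  evals_u <- matrix(0, nu, 3)
  pev_u <- matrix(0, nu, 3)
  for (i in seq_len(nu)) {
    es <- eigen(vec6_to_tensor(vec6[uidx[i], ]), symmetric = TRUE)
    evals_u[i, ] <- es$values            # descending
    pev_u[i, ] <- es$vectors[, 1]
  }
  evals <- evals_u[map, , drop = FALSE]
  pev <- pev_u[map, , drop = FALSE]

  lam <- pmax(evals, 0)                  # clamped copy for FA / color-FA only
  ss <- rowSums(lam^2)
  mn <- rowMeans(lam)
  fa <- ifelse(ss > 0, sqrt(1.5 * rowSums((lam - mn)^2) / ss), 0)
  fa <- pmin(pmax(fa, 0), 1)
  fa[flagged] <- 0
  color <- abs(pev) * fa
  evals[flagged, ] <- 0
  pev[flagged, ] <- 0

  structure(
    list(
      tensor = array(vec6, dim = c(dim3, 6)),
      eigenvalues = array(evals, dim = c(dim3, 3)),
      pev = array(pev, dim = c(dim3, 3)),
      fa = array(fa, dim = dim3),
      color_fa = array(pmin(color, 1), dim = c(dim3, 3)),
      flagged = array(flagged, dim = dim3),
      voxel_size = as.numeric(voxel_size),
      affine = affine %||% diag(c(voxel_size, 1))
    ),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$fa)
  cat(sprintf("<tensor_field> %dx%dx%d grid, %d flagged voxels, FA range [%.3f, %.3f]\n",
              d[1], d[2], d[3], sum(x$flagged), min(x$fa), max(x$fa)))
  invisible(x)
}
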