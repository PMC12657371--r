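test_that("FA matches the closed-form eigenvalue formula", {
  # independent arithmetic: FA of (1.7, 0.3, 0.3)e-3
  lam <- c(1.7, 0.3, 0.3) * 1e-3
  fa_oracle <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(fa_oracle, 0.7990222, tolerance = 1e-6)

  sp <- dwi_phantom_spec(grid_shape = c(8, 8, 8), layout = "alps",
                         scheme = axis_scheme())
  ph <- make_dwi_phantom(sp)
  tf <- fit_tensors(ph$dwi)
  fiber <- ph$labels == 2
  expect_equal(unique(round(tf$fa[fiber], 9)), round(fa_oracle, 9))

  # isotropic voxels have FA exactly 0
  iso <- ph$labels == 1
  expect_equal(max(abs(tf$fa[iso])), 0, tolerance = 1e-9)
})

test_that("color-FA encodes the principal axis scaled by FA", {
  sp <- dwi_phantom_spec(grid_shape = c(8, 8, 8), layout = "alps",
                         scheme = axis_scheme())
  ph <- make_dwi_phantom(sp)
  tf <- fit_tensors(ph$dwi)
  expect_true(all(tf$color_fa >= 0 & tf$color_fa <= 1))
  # projection block: principal axis z, so only the blue channel is non-zero
  v <- which(ph$labels == 2, arr.ind = TRUE)[1, ]
  rgb <- tf$color_fa[v[1], v[2], v[3], ]
  expect_equal(rgb[1:2], c(0, 0), tolerance = 1e-6)
  expect_equal(rgb[3], tf$fa[v[1], v[2], v[3]], tolerance = 1e-6)
})

test_that("degenerate inputs are rejected or flagged", {
  # fewer than 6 unique directions is rejected at construction
  sch <- axis_scheme()
  sig <- array(100, dim = c(3, 3, 3, 3))
  expect_error(
    diffusion_volume(sig, sch$bvalues[1:3], sch$bvecs[, 1:3]),
    "6 unique"
  )
  # all-zero voxel signal: flagged, zero tensor, excluded downstream
  ph <- make_dwi_phantom(dwi_phantom_spec(grid_shape = c(6, 6, 6),
                                          layout = "isotropic",
                                          scheme = axis_scheme()))
  sig <- ph$dwi$signal
  sig[1, 1, 1, ] <- 0
  dwi <- diffusion_volume(sig, ph$dwi$bvalues, ph$dwi$bvecs)
  tf <- fit_tensors(dwi)
  expect_true(tf$flagged[1, 1, 1])
  expect_equal(sum(tf$flagged), 1L)
  expect_equal(tf$tensor[1, 1, 1, ], rep(0, 6))
})

test_that("weighted and ordinary fits agree on noiseless data and eigenvalues sort descending", {
  sp <- dwi_phantom_spec(grid_shape = c(6, 6, 6), layout = "alps",
                         scheme = dwi_scheme(n_dirs = 12, n_b0 = 2))
  ph <- make_dwi_phantom(sp)
  tw <- fit_tensors(ph$dwi, method = "wls")
  to <- fit_tensors(ph$dwi, method = "ols")
  expect_equal(tw$tensor, to$tensor, tolerance = 1e-12)
  ev <- matrix(tw$eigenvalues, ncol = 3)
  expect_true(all(ev[, 1] >= ev[, 2] & ev[, 2] >= ev[, 3]))
  expect_true(all(tw$fa >= 0 & tw$fa <= 1))
})
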