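make_uniform_field <- function(dim3 = c(11, 11, 11), diag6 = c(1, 2, 3, 0, 0, 0) * 1e-3) {
  nv <- prod(dim3)
  glymphkit:::tensor_field_from_vec6(
    matrix(rep(diag6, each = nv), nv, 6), dim3, c(1, 1, 1))
}

test_that("spherical ROI voxel selection matches brute-force lattice counting", {
  field <- make_uniform_field()
  roi <- list(x = 5, y = 5, z = 5, diameter = 5)
  idx <- sphere_roi(roi, field)
  # independent oracle: count lattice points within 2.5 mm
  g <- as.matrix(expand.grid(x = 0:10, y = 0:10, z = 0:10))
  oracle <- sum((g[, 1] - 5)^2 + (g[, 2] - 5)^2 + (g[, 3] - 5)^2 <= 2.5^2)
  expect_equal(length(idx), oracle)
  expect_equal(length(idx), 81L)

  # sub-voxel diameter centered on a voxel center selects exactly that voxel
  tiny <- sphere_roi(list(x = 5, y = 5, z = 5, diameter = 0.5), field)
  expect_equal(length(tiny), 1L)
  expect_error(sphere_roi(list(x = 50, y = 5, z = 5, diameter = 5), field),
               "outside the volume")
})

test_that("ROI diffusivity extraction averages the diagonal exactly", {
  field <- make_uniform_field()
  idx <- sphere_roi(list(x = 5, y = 5, z = 5, diameter = 5), field)
  d <- extract_diffusivities(field, idx)
  expect_equal(unname(d), c(1e-3, 2e-3, 3e-3))

  # random tensor field: mean must equal a per-voxel averaging oracle
  set.seed(42)
  dim3 <- c(7, 7, 7)
  vec6 <- matrix(stats::rnorm(prod(dim3) * 6, 1e-3, 1e-4), prod(dim3), 6)
  rf <- glymphkit:::tensor_field_from_vec6(vec6, dim3, c(1, 1, 1))
  idx <- sphere_roi(list(x = 3, y = 3, z = 3, diameter = 4), rf)
  d <- extract_diffusivities(rf, idx)
  oracle <- colMeans(vec6[idx, 1:3, drop = FALSE])
  expect_equal(unname(d), unname(oracle), tolerance = 1e-12)
})

test_that("the ALPS ratio follows its defining arithmetic", {
  expect_equal(alps_index(1e-3, 1e-3, 1e-3, 1e-3)$alps_index, 1)
  # hand arithmetic: mean(1.6, 1.6) / mean(1.0, 1.2) = 1.6 / 1.1
  expect_equal(alps_index(1.6e-3, 1.6e-3, 1.0e-3, 1.2e-3)$alps_index,
               1.6 / 1.1, tolerance = 1e-12)
  expect_error(alps_index(1e-3, 1e-3, 0, 0), "denominator")

  # scale invariance: k * all four diffusivities leaves the index unchanged
  set.seed(7)
  for (i in 1:20) {
    d4 <- stats::runif(4, 0.5e-3, 2e-3)
    k <- stats::runif(1, 0.1, 10)
    expect_equal(alps_index(d4[1], d4[2], d4[3], d4[4])$alps_index,
                 alps_index(k * d4[1], k * d4[2], k * d4[3], k * d4[4])$alps_index,
                 tolerance = 1e-12)
  }
})

test_that("the full phantom pipeline returns the eigenvalue-ratio oracle", {
  sp <- dwi_phantom_spec(grid_shape = c(24, 24, 24), layout = "alps_oracle")
  ph <- make_dwi_phantom(sp)
  res <- compute_alps(fit_tensors(ph$dwi), phantom_roi_table(sp))
  expect_equal(res$alps_index, 1.7 / 0.3, tolerance = 1e-6)

  # isotropic volume: index is exactly 1
  spi <- dwi_phantom_spec(grid_shape = c(12, 12, 12), layout = "isotropic")
  phi <- make_dwi_phantom(spi)
  roi <- tibble::tibble(fiber_type = c("projection", "association"),
                        hemisphere = "left", x = 5.5, y = 5.5, z = 5.5,
                        diameter = 5)
  resi <- compute_alps(fit_tensors(phi$dwi), roi)
  expect_equal(resi$alps_index, 1, tolerance = 1e-6)
})

test_that("a noisy isotropic phantom stays within sampling error of index 1", {
  sp <- dwi_phantom_spec(grid_shape = c(16, 16, 16), layout = "isotropic",
                         snr = 20, seed = 31)
  ph <- make_dwi_phantom(sp)
  roi <- tibble::tibble(fiber_type = c("projection", "association"),
                        hemisphere = "left", x = 7.5, y = 7.5, z = 7.5,
                        diameter = 5)
  res <- compute_alps(fit_tensors(ph$dwi), roi)
  expect_equal(res$alps_index, 1, tolerance = 0.1)
})
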