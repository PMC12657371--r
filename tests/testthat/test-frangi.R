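test_that("the analytic symmetric eigensolver matches eigen()", {
  set.seed(8)
  for (i in 1:50) {
    A <- matrix(stats::rnorm(9), 3, 3)
    A <- (A + t(A)) / 2
    lam <- glymphkit:::symm3_eigen_absorted(A[1, 1], A[2, 2], A[3, 3],
                                            A[1, 2], A[1, 3], A[2, 3])
    ref <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(as.vector(lam)), sort(ref), tolerance = 1e-10)
    expect_true(all(diff(abs(as.vector(lam))) >= -1e-10))  # |l1|<=|l2|<=|l3|
  }
  # degenerate: multiples of the identity
  lam <- glymphkit:::symm3_eigen_absorted(2, 2, 2, 0, 0, 0)
  expect_equal(as.vector(lam), c(2, 2, 2))
})

test_that("vesselness is zero on uniform volumes and bounded in [0, 1]", {
  flat <- frangi_vesselness(array(5, dim = c(12, 12, 12)),
                            voxel_size = c(1, 1, 1))
  expect_equal(max(flat$v), 0)
  v <- std_vesselness_noisy$v
  expect_true(all(v >= 0 & v <= 1))
})

test_that("dark tubes respond strongly; bright tubes are gated out", {
  ph <- std_phantom_noiseless
  v0 <- std_vesselness_noiseless$v
  expect_gt(mean(v0[ph$truth_mask]), 0.2)
  expect_lt(mean(v0[!ph$truth_mask]), 1e-3)

  # with 5% noise the on-tube/background contrast ratio still exceeds 10
  vn <- std_vesselness_noisy$v
  tn <- std_phantom_noisy$truth_mask
  expect_gte(mean(vn[tn]) / mean(vn[!tn]), 10)

  # polarity gate: an intensity-inverted phantom has no dark-tube response
  inv <- compute_epc(structural_pair(ph$pair$t2w, ph$pair$t1w))
  vb <- frangi_vesselness(inv)                     # bright tubes, dark polarity
  expect_equal(mean(vb$v[ph$truth_mask]), 0, tolerance = 1e-8)
  vb2 <- frangi_vesselness(inv, frangi_params(polarity = "bright"))
  expect_gt(mean(vb2$v[ph$truth_mask]), 0.2)
})

test_that("adding scales can only increase the max-over-scales response", {
  epc <- compute_epc(std_phantom_noiseless$pair)
  v_small <- frangi_vesselness(epc, frangi_params(scales = c(0.5, 1)))$v
  v_full <- frangi_vesselness(epc, frangi_params(scales = c(0.5, 1, 1.5, 2)))$v
  expect_true(all(v_full - v_small >= -1e-12))
})

test_that("the response is robust to 90-degree tube rotation", {
  atlas <- synthetic_atlas()
  lookup <- atlas$lookup
  code <- lookup$code[lookup$region == "putamen" & lookup$hemisphere == "left"]
  pos <- which(atlas$labels == code, arr.ind = TRUE)
  mid <- colMeans(pos) - 1
  mk <- function(axis) {
    start <- mid; end <- mid                     # same 6-mm length on each axis
    start[axis] <- mid[axis] - 3; end[axis] <- mid[axis] + 3
    ph <- make_pvs_phantom(pvs_phantom_spec(
      atlas = atlas,
      tubes = list(list(start = start, end = end, radius = 1.5,
                        region = "putamen", hemisphere = "left")),
      intensity_model = list(noise_sd = 0)))
    v <- frangi_vesselness(compute_epc(ph$pair))$v
    # compare response over the tube interior (exclude endpoint caps)
    core <- ph$truth_mask
    mean(v[core])
  }
  vz <- mk(3); vy <- mk(2)
  expect_equal(vz, vy, tolerance = 0.05)
})
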