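test_that("26-connected labelling merges diagonal neighbours and splits islands", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE        # pure diagonal contact
  m[5, 5, 5] <- TRUE                            # isolated island
  lab <- glymphkit:::label_components_26(m)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_false(lab[5, 5, 5] == lab[1, 1, 1])
  expect_equal(max(lab), 2L)
})

test_that("thresholding and cluster pruning behave at the extremes", {
  v <- std_vesselness_noiseless
  tissue <- std_phantom_noiseless$atlas$tissue
  expect_false(any(segment_pvs(v, tissue, threshold = 1)))        # v < 1 everywhere
  expect_false(any(segment_pvs(v, tissue, threshold = 0.1,
                               min_cluster_voxels = 1e6)))        # prune all
  expect_error(segment_pvs(v, array(FALSE, dim = dim(v$v))), "empty")
  expect_error(segment_pvs(v, tissue, threshold = 0), "threshold")
})

test_that("default segmentation recovers the phantom tubes", {
  seg0 <- segment_pvs(std_vesselness_noiseless,
                      std_phantom_noiseless$atlas$tissue)
  expect_gte(dice_coefficient(seg0, std_phantom_noiseless$truth_mask), 0.7)

  segn <- segment_pvs(std_vesselness_noisy, std_phantom_noisy$atlas$tissue)
  sens <- sum(segn & std_phantom_noisy$truth_mask) /
    sum(std_phantom_noisy$truth_mask)
  expect_gte(sens, 0.9)
})

test_that("volume fractions follow the defining arithmetic", {
  atlas <- synthetic_atlas()
  code <- atlas$lookup$code[atlas$lookup$region == "putamen" &
                            atlas$lookup$hemisphere == "left"]
  reg_idx <- which(atlas$labels == code)
  # 10 PVS voxels of 1 mm^3 against a 1000-voxel tissue denominator
  atlas$tissue[] <- FALSE
  atlas$tissue[sample(which(atlas$labels > 0), 1000)] <- TRUE
  mask <- array(FALSE, dim = dim(atlas$labels))
  mask[reg_idx[1:10]] <- TRUE
  vf <- pvs_volume_fraction(mask, atlas)
  row <- vf[vf$region == "putamen" & vf$hemisphere == "left", ]
  expect_equal(row$pvs_volume_mm3, 10)
  expect_equal(row$tissue_volume_mm3, 1000)
  expect_equal(row$vf_percent, 1.0)

  # empty mask: all fractions zero
  vf0 <- pvs_volume_fraction(array(FALSE, dim = dim(atlas$labels)), atlas)
  expect_true(all(vf0$vf_percent == 0))

  # zero tissue volume is an error
  atlas$tissue[] <- FALSE
  expect_error(pvs_volume_fraction(mask, atlas), "zero GM\\+WM volume")
})

test_that("the basal-ganglia aggregate equals the sum of its subdivisions", {
  seg <- segment_pvs(std_vesselness_noiseless,
                     std_phantom_noiseless$atlas$tissue)
  vf <- pvs_volume_fraction(seg, std_phantom_noiseless$atlas)
  for (h in c("left", "right", "total")) {
    bg <- vf[vf$region == "BG" & vf$hemisphere == h, ]
    subs <- vf[vf$region %in% c("caudate", "putamen", "pallidum", "amygdala") &
               vf$hemisphere == h, ]
    expect_equal(bg$pvs_volume_mm3, sum(subs$pvs_volume_mm3))
    expect_equal(bg$vf_percent, sum(subs$pvs_volume_mm3) / bg$tissue_volume_mm3 * 100)
    expect_equal(bg$vf_percent, sum(subs$vf_percent), tolerance = 1e-12)
  }
  # region-local denominators are also available
  vfr <- pvs_volume_fraction(seg, std_phantom_noiseless$atlas,
                             denominator = "region")
  expect_true(all(vfr$vf_percent >= 0 & vfr$vf_percent <= 100))
})

test_that("ground-truth volume fraction equals the voxel count ratio exactly", {
  ph <- std_phantom_noiseless
  vf <- pvs_volume_fraction(ph$truth_mask, ph$atlas)
  truth_vf <- vf$vf_percent[vf$region == "BG" & vf$hemisphere == "total"]
  in_bg <- ph$tube_table$region %in% c("caudate", "putamen", "pallidum",
                                       "amygdala")
  expect_equal(truth_vf,
               100 * sum(ph$tube_table$voxel_count[in_bg]) /
                 sum(ph$atlas$tissue))
})

test_that("voxelized cylinder volume converges to the analytic volume", {
  # r = 2 mm, L = 15 mm cylinder sampled at 1 mm and 0.25 mm
  vol_at <- function(h) {
    d <- round(c(24, 24, 24) / h)
    m <- glymphkit:::voxelize_cylinder(d, rep(h, 3),
                                       start = c(12, 12, 4.1),
                                       end = c(12, 12, 19.1), radius = 2)
    sum(m) * h^3
  }
  analytic <- pi * 4 * 15
  err <- function(h) abs(vol_at(h) - analytic) / analytic
  expect_lt(err(0.25), err(1))       # finer grid, smaller error
  expect_lt(err(0.25), 0.05)
})
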