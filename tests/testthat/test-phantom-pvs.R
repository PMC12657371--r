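test_that("tube voxelization matches the brute-force point-in-cylinder oracle", {
  atlas <- synthetic_atlas(c(28, 28, 20))
  lookup <- atlas$lookup
  code <- lookup$code[lookup$region == "putamen" & lookup$hemisphere == "left"]
  pos <- which(atlas$labels == code, arr.ind = TRUE)
  mid <- colMeans(pos) - 1                     # world mm at voxel_size 1
  start <- c(mid[1], mid[2], min(pos[, 3]))
  end <- c(mid[1], mid[2], max(pos[, 3]) - 2)
  tube <- list(start = start, end = end, radius = 1,
               region = "putamen", hemisphere = "left")
  ph <- make_pvs_phantom(pvs_phantom_spec(
    atlas = atlas, tubes = list(tube),
    intensity_model = list(noise_sd = 0)))
  oracle <- cylinder_count_brute_force(dim(atlas$labels), atlas$voxel_size,
                                       start, end, 1)
  expect_equal(sum(ph$truth_mask), oracle)
  expect_gt(oracle, 0)
})

test_that("phantom intensities follow the tube contrast model", {
  ph <- std_phantom_noiseless
  im <- list(t1_bg = 100, t2_bg = 100, t1_decrement = 30, t2_increment = 30)
  expect_equal(unique(as.vector(ph$pair$t1w[ph$truth_mask])), im$t1_bg - im$t1_decrement)
  expect_equal(unique(as.vector(ph$pair$t2w[ph$truth_mask])), im$t2_bg + im$t2_increment)
  expect_equal(unique(as.vector(ph$pair$t1w[!ph$truth_mask])), im$t1_bg)
})

test_that("zero tubes give an empty mask and uniform volumes", {
  ph <- make_pvs_phantom(pvs_phantom_spec(
    tubes = list(), intensity_model = list(noise_sd = 0)))
  expect_false(any(ph$truth_mask))
  expect_equal(length(unique(as.vector(ph$pair$t1w))), 1L)
  expect_equal(nrow(ph$tube_table), 0L)
})

test_that("disjoint tube volumes add and invalid tubes are rejected", {
  atlas <- synthetic_atlas()
  tubes <- pvs_phantom_spec(atlas = atlas)$tubes    # standard disjoint set
  both <- make_pvs_phantom(pvs_phantom_spec(
    atlas = atlas, tubes = tubes, intensity_model = list(noise_sd = 0)))
  singles <- vapply(seq_along(tubes), function(i) {
    one <- make_pvs_phantom(pvs_phantom_spec(
      atlas = atlas, tubes = tubes[i], intensity_model = list(noise_sd = 0)))
    sum(one$truth_mask)
  }, numeric(1))
  expect_equal(sum(both$truth_mask), sum(singles))

  # tube leaving its declared region
  expect_error(make_pvs_phantom(pvs_phantom_spec(
    atlas = atlas,
    tubes = list(list(start = c(1, 1, 1), end = c(30, 30, 25), radius = 1,
                      region = "putamen", hemisphere = "left")))),
    "leaves its declared region")
  # tube endpoint outside the volume
  expect_error(make_pvs_phantom(pvs_phantom_spec(
    atlas = atlas,
    tubes = list(list(start = c(0, 0, 0), end = c(0, 0, 200), radius = 1,
                      region = "putamen", hemisphere = "left")))),
    "outside the atlas extent")
  # radius below half a voxel
  expect_error(pvs_phantom_spec(atlas = atlas,
    tubes = list(list(start = c(1, 1, 1), end = c(1, 1, 5), radius = 0.2,
                      region = "putamen", hemisphere = "left"))),
    "below half the voxel size")
})

test_that("structural phantom noise is reproducible under the seed", {
  sp <- pvs_phantom_spec(seed = 11)
  expect_identical(make_pvs_phantom(sp)$pair$t1w, make_pvs_phantom(sp)$pair$t1w)
})
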