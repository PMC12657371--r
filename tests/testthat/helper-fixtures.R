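# Shared phantom fixtures, built once per test run. The "standard" tube
# phantom (radii 1-2 mm, 30% contrast) is used by the Frangi, segmentation
# and acceptance tests in its noiseless and 5%-noise variants.

std_phantom_noiseless <- make_pvs_phantom(
  pvs_phantom_spec(intensity_model = list(noise_sd = 0), seed = 101)
)
std_vesselness_noiseless <- frangi_vesselness(compute_epc(std_phantom_noiseless$pair))

std_phantom_noisy <- make_pvs_phantom(pvs_phantom_spec(seed = 202))
std_vesselness_noisy <- local({
  t1f <- nlm_filter(std_phantom_noisy$pair$t1w)
  t2f <- nlm_filter(std_phantom_noisy$pair$t2w)
  frangi_vesselness(compute_epc(structural_pair(
    t1f, t2f, voxel_size = std_phantom_noisy$pair$voxel_size)))
})
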