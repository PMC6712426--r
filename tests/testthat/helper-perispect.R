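# Shared fixtures: shipped priors and the study acquisition protocol.
pri <- load_priors()
mets3 <- pri$metabolites
water3 <- pri$water
acq_default <- acquisition_params()

# smaller/faster variant for unit tests; 1024 points keeps ~10 samples per
# integration window
acq_small <- acquisition_params(n_points = 1024, grid_shape = c(3L, 3L))

# a small noiseless phantom (1 mm voxels) reused by several tests
small_phantom <- function(hematoma_ml = 1.0, edema_ml = 2.38, icv_ml = 70.3,
                          voxel_mm = 1.0, shape = c(96L, 96L, 96L), ...) {
  simulate_flair_phantom(
    phantom_spec(image_shape = shape, voxel_mm = voxel_mm, icv_ml = icv_ml,
                 hematoma_ml = hematoma_ml, edema_ml = edema_ml, ...))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
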