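test_that("an empty voxel yields a flat suppressed spectrum and a water-only companion", {
  v <- simulate_spectrum(ground_truth_voxel("CONTRA", c(NAA = 0)),
                         mets3, water3, acq_default)
  expect_true(all(Mod(v$suppressed$values) == 0))
  expect_gt(max(Re(v$unsuppressed$values)), 0)
  # water line area equals the injected reference area (full-axis integral,
  # minus the tail fraction outside the axis)
  aw_num <- pracma::trapz(v$unsuppressed$ppm, Re(v$unsuppressed$values))
  expect_rel_equal(aw_num, v$aw, 0.005)
})

test_that("a metabolite identical to water in protons and relaxation gets Am = Aw", {
  # symmetry of the water-referencing relation
  twin <- metabolite_spec("twin", ppm = 2.5, n_protons = water3$n_protons,
                          t1 = water3$t1, t2 = water3$t2)
  v <- simulate_spectrum(
    ground_truth_voxel("CONTRA", c(twin = water3$cw)),
    list(twin = twin), water3, acq_default)
  expect_equal(unname(v$am[["twin"]]), v$aw, tolerance = 1e-12)
})

test_that("injected areas invert the concentration equation (closed form vs rendered)", {
  # independent arithmetic evaluation of the inverted relation
  tr <- 2000; te <- 144
  num <- 3 * (1 - exp(-tr / 1470)) * exp(-te / 247)     # NAA
  den <- 2 * (1 - exp(-tr / 1200)) * exp(-te / 80)      # water
  am_expected <- 13.7 * 1000 * num / (den * 55510 * 0.71)
  v <- simulate_spectrum(ground_truth_voxel("CONTRA", c(NAA = 13.7)),
                         mets3, water3, acq_default, aw_scale = 1000)
  expect_equal(unname(v$am[["NAA"]]), am_expected, tolerance = 1e-12)
  # numerical integration of the rendered Lorentzian reproduces it to <0.5%
  am_num <- pracma::trapz(v$suppressed$ppm, Re(v$suppressed$values))
  expect_rel_equal(am_num, am_expected, 0.005)
})

test_that("increasing the true concentration strictly increases the peak area", {
  areas <- vapply(c(1, 5, 10, 20), function(cm) {
    v <- simulate_spectrum(ground_truth_voxel("PHE", c(NAA = cm)),
                           mets3, water3, acq_default)
    unname(v$am[["NAA"]])
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("simulation rejects impossible inputs with explicit messages", {
  expect_error(ground_truth_voxel("PHE", c(NAA = -1)),
               class = "perispect_validation_error")
  out_met <- list(far = metabolite_spec("far", ppm = 9.9, n_protons = 1,
                                        t1 = 1000, t2 = 100))
  acq_narrow <- acquisition_params(bandwidth = 600, n_points = 256)
  expect_error(
    simulate_spectrum(ground_truth_voxel("PHE", c(far = 5)), out_met,
                      water3, acq_narrow),
    regexp = "outside the spectral axis")
})

test_that("spectrum simulation is bit-reproducible under a fixed seed", {
  t <- ground_truth_voxel("PHE", c(NAA = 9.7, Cr = 3.62), snr = 15)
  v1 <- simulate_spectrum(t, mets3, water3, acq_default, seed = 11)
  v2 <- simulate_spectrum(t, mets3, water3, acq_default, seed = 11)
  v3 <- simulate_spectrum(t, mets3, water3, acq_default, seed = 12)
  expect_identical(v1$suppressed$values, v2$suppressed$values)
  expect_identical(v1$unsuppressed$values, v2$unsuppressed$values)
  expect_false(identical(v1$suppressed$values, v3$suppressed$values))
})

test_that("the per-channel noise level matches the stated SNR definition", {
  t <- ground_truth_voxel("CONTRA", c(NAA = 13.7), snr = 20)
  v <- simulate_spectrum(t, mets3, water3, acq_default, seed = 5)
  # empirical noise SD from the signal-free spectral tails
  n <- length(v$suppressed$values)
  tails <- c(1:200, (n - 199):n)
  h_naa <- max(Re(simulate_spectrum(
    ground_truth_voxel("CONTRA", c(NAA = 13.7)), mets3, water3,
    acq_default)$suppressed$values))
  expect_rel_equal(stats::sd(Re(v$suppressed$values[tails])), h_naa / 20, 0.2)
  h_w <- max(Re(simulate_spectrum(
    ground_truth_voxel("CONTRA", c(NAA = 0)), mets3, water3,
    acq_default)$unsuppressed$values))
  expect_rel_equal(stats::sd(Re(v$unsuppressed$values[tails])), h_w / 20, 0.2)
})

test_that("CSI grids respect shape, locality of truth, and container round trips", {
  tm <- matrix(list(), 3, 3)
  for (i in 1:3) for (j in 1:3) {
    tm[[i, j]] <- ground_truth_voxel("CONTRA", c(NAA = 0))
  }
  tm[[2, 2]] <- ground_truth_voxel("PHE", c(NAA = 9.7), snr = Inf)
  g <- simulate_csi_grid(tm, mets3, water3, acq_small, seed = 1)
  expect_equal(dim(g$suppressed), c(1024L, 3L, 3L))
  # only the PHE voxel carries signal
  for (i in 1:3) for (j in 1:3) {
    m <- max(Mod(g$suppressed[, i, j]))
    if (i == 2 && j == 2) expect_gt(m, 0) else expect_equal(m, 0)
  }
  expect_equal(g$regions[2, 2], "PHE")
  # shape mismatch is rejected
  expect_error(simulate_csi_grid(tm[1:2, 1:2, drop = FALSE], mets3, water3,
                                 acq_small),
               class = "perispect_validation_error")
  # container round trip
  p <- tempfile(fileext = ".csi.json")
  write_csi(g, p)
  g2 <- read_csi(p)
  expect_lt(max(Mod(g$suppressed - g2$suppressed)), 1e-10)
  expect_lt(max(Mod(g$unsuppressed - g2$unsuppressed)), 1e-10)
  expect_equal(g$ppm, g2$ppm, tolerance = 1e-12)
  expect_identical(g$regions, g2$regions)
  expect_equal(g2$truth[[2, 2]]$concentrations, c(NAA = 9.7))
  unlink(p)
})
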