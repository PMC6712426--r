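clean_voxel <- function(phase0 = 0, phase1 = 0,
                        conc = c(NAA = 10, Cr = 8, Cho = 2), snr = Inf,
                        seed = NULL) {
  simulate_spectrum(ground_truth_voxel("PHE", conc, phase0 = phase0,
                                       phase1 = phase1, snr = snr),
                    mets3, water3, acq_default, seed = seed)
}

test_that("an already-phased spectrum yields phase estimates near zero", {
  pc <- phase_correct(clean_voxel()$suppressed)
  expect_lt(abs(pc$phi0), 0.05)
  expect_lt(abs(pc$phi1), 0.05)
  expect_false(pc$low_confidence)
})

test_that("injected zero/first-order phases are recovered within 1 deg / 0.5 deg/ppm", {
  cases <- list(c(37, 5), c(-60, 12), c(85, -18), c(170, 0), c(-120, -9))
  for (ph in cases) {
    pc <- phase_correct(clean_voxel(ph[1], ph[2])$suppressed)
    expect_lt(abs(pc$phi0 - ph[1]), 1)
    expect_lt(abs(pc$phi1 - ph[2]), 0.5)
  }
})

test_that("re-applying the estimated phases reproduces the observed spectrum", {
  v <- clean_voxel(37, 5, snr = 30, seed = 4)
  pc <- phase_correct(v$suppressed)
  back <- apply_phase(pc$spectrum, pc$phi0, pc$phi1)
  expect_lt(max(Mod(back$values - v$suppressed$values)), 1e-10)
})

test_that("a noise-only spectrum is flagged low-confidence", {
  v <- simulate_spectrum(ground_truth_voxel("CONTRA", c(NAA = 0), snr = 20),
                         mets3, water3, acq_default, seed = 9)
  pc <- phase_correct(v$suppressed)
  expect_true(pc$low_confidence)
})

test_that("peak integration matches the closed-form Lorentzian area", {
  # analytic unit-area Lorentzian, FWHM much smaller than the window
  acq <- acq_default
  ppm <- ppm_axis(acq)
  gam <- (5 / acq$field_ppm_hz) / 2
  y <- (gam / pi) / ((ppm - 2.5)^2 + gam^2)
  s <- spectrum(complex(real = y), ppm)
  hw <- 10 * (2 * gam)  # +-10 FWHM
  pa <- integrate_peak(s, 2.5, half_width_ppm = hw)
  # expected value from the closed-form tail fraction, minus the area the
  # edge-anchored baseline removes (2 * tail height * width, trapezoid)
  captured <- (2 / pi) * atan(hw / gam)
  edge <- (gam / pi) / (hw^2 + gam^2)
  expected <- captured - 2 * hw * edge
  expect_rel_equal(pa$area, expected, 0.01)
})

test_that("a flat spectrum integrates to zero and bad windows are rejected", {
  ppm <- ppm_axis(acq_default)
  s <- spectrum(complex(real = rep(0, length(ppm))), ppm)
  expect_equal(integrate_peak(s, 3.0)$area, 0)
  expect_error(integrate_peak(s, max(ppm) + 1),
               class = "perispect_validation_error")
})

test_that("integration is linear in spectrum amplitude", {
  v <- clean_voxel()
  s1 <- v$suppressed
  s3 <- spectrum(3 * s1$values, s1$ppm)
  a1 <- integrate_peak(s1, 2.01)$area
  a3 <- integrate_peak(s3, 2.01)$area
  expect_equal(a3, 3 * a1, tolerance = 1e-12)
})

test_that("the integral is robust to sub-resolution shifts of the peak centre", {
  acq <- acq_default
  dppm <- acq$bandwidth / acq$n_points / acq$field_ppm_hz
  areas <- vapply(c(0, 0.25, 0.5, 0.75) * dppm, function(off) {
    m <- metabolite_spec("NAA", ppm = 2.01 + off, n_protons = 3,
                         t1 = 1470, t2 = 247)
    v <- simulate_spectrum(ground_truth_voxel("PHE", c(NAA = 10)),
                           list(NAA = m), water3, acq)
    integrate_peak(v$suppressed, 2.01 + off)$area
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.005)
})

test_that("two peaks 0.16 ppm apart integrate within 5% of their isolated values", {
  pair <- clean_voxel(conc = c(Cr = 8, Cho = 8 * 0.0713268 / 0.3090628))
  # equal areas for the two lines (concentration scaled by the relaxation
  # factor ratio), the harder case for cross-contamination
  iso_cr <- clean_voxel(conc = c(Cr = 8))
  a_pair <- integrate_peak(pair$suppressed, 3.03)$area
  a_iso <- integrate_peak(iso_cr$suppressed, 3.03)$area
  expect_rel_equal(a_pair, a_iso, 0.05)
  iso_cho <- clean_voxel(conc = c(Cho = 8 * 0.0713268 / 0.3090628))
  b_pair <- integrate_peak(pair$suppressed, 3.19)$area
  b_iso <- integrate_peak(iso_cho$suppressed, 3.19)$area
  expect_rel_equal(b_pair, b_iso, 0.05)
})

test_that("the water measurement recovers the injected reference area", {
  v <- clean_voxel(phase0 = 25)
  pa <- measure_water(v$unsuppressed)
  # both channels share the finite-window attenuation; compare against the
  # same-window integral of the metabolite channel normalised by truth
  a_naa <- integrate_peak(phase_correct(v$suppressed)$spectrum, 2.01)$area
  expect_rel_equal(pa$area / a_naa, v$aw / v$am[["NAA"]], 0.01)
  expect_length(pa$flags, 0)
})

test_that("water off-centre or absent is flagged", {
  # water rendered away from 4.7 ppm
  off_water <- water_reference(ppm = 4.95, t1 = water3$t1, t2 = water3$t2,
                               cw = water3$cw)
  v <- simulate_spectrum(ground_truth_voxel("PHE", c(NAA = 10)),
                         mets3, off_water, acq_default)
  pa <- measure_water(v$unsuppressed, center_ppm = 4.7)
  expect_true("off_center" %in% pa$flags)
  # flat spectrum
  ppm <- ppm_axis(acq_default)
  flat <- spectrum(complex(real = rep(0, length(ppm))), ppm)
  pf <- measure_water(flat)
  expect_equal(pf$area, 0)
  expect_true("low_signal" %in% pf$flags)
})

test_that("water-ratio QC reports unit ratios for equal water and detects excess", {
  mk_grid <- function(aw_phe_factor = 1) {
    tm <- matrix(list(), 3, 3)
    for (i in 1:3) for (j in 1:3) {
      tm[[i, j]] <- ground_truth_voxel("CONTRA", c(NAA = 10))
    }
    g <- simulate_csi_grid(tm, mets3, water3, acq_small, seed = 2)
    if (aw_phe_factor != 1) {
      # inflate the PHE voxel's water line
      g$unsuppressed[, 1, 1] <- g$unsuppressed[, 1, 1] * aw_phe_factor
    }
    g
  }
  voxels <- list(PHE = c(1L, 1L), ATNE = c(2L, 2L), CONTRA = c(3L, 3L))
  qc1 <- water_ratio_qc(list(`1` = mk_grid()), voxels)
  expect_equal(qc1$ratio, rep(1, 3), tolerance = 1e-6)
  qc2 <- water_ratio_qc(list(`1` = mk_grid(1.2)), voxels)
  expect_equal(qc2$ratio[qc2$region == "PHE"], 1.2, tolerance = 1e-6)
  # empty voxel -> undefined, flagged
  tm <- matrix(list(), 3, 3)
  for (i in 1:3) for (j in 1:3) tm[[i, j]] <- ground_truth_voxel("CONTRA", c(NAA = 0))
  g0 <- simulate_csi_grid(tm, mets3, water3, acq_small, seed = 3)
  g0$unsuppressed[, 1, 1] <- 0 + 0i
  qc3 <- water_ratio_qc(list(`1` = g0), voxels)
  expect_true(qc3$flag[qc3$region == "PHE"])
  expect_true(is.na(qc3$ratio[qc3$region == "PHE"]))
})
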