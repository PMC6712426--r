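test_that("the relaxation factor reduces to the proton ratio in the TE->0, TR->inf limit", {
  acq_lim <- acquisition_params(tr = 1e9, te = 1e-9)
  same <- metabolite_spec("m", ppm = 2, n_protons = 2, t1 = water3$t1,
                          t2 = water3$t2)
  expect_equal(relaxation_factor(same, water3, acq_lim), 1, tolerance = 1e-9)
  cho_like <- metabolite_spec("cho", ppm = 3.19, n_protons = 9,
                              t1 = water3$t1, t2 = water3$t2)
  expect_equal(relaxation_factor(cho_like, water3, acq_lim), 2 / 9,
               tolerance = 1e-9)
})

test_that("the relaxation factor matches independent scalar arithmetic at TR/TE = 2000/144", {
  # oracle: plain arithmetic, written out without the package's helpers
  f_oracle <- function(nm, t1m, t2m) {
    (2 * (1 - exp(-2000 / 1200)) * exp(-144 / 80)) /
      (nm * (1 - exp(-2000 / t1m)) * exp(-144 / t2m))
  }
  expect_equal(relaxation_factor(mets3$NAA, water3, acq_default),
               f_oracle(3, 1470, 247), tolerance = 1e-12)
  expect_equal(relaxation_factor(mets3$Cr, water3, acq_default),
               f_oracle(3, 1460, 152), tolerance = 1e-12)
  expect_equal(relaxation_factor(mets3$Cho, water3, acq_default),
               f_oracle(9, 1200, 217), tolerance = 1e-12)
})

test_that("self-referencing returns the water concentration and zero area gives zero", {
  same <- metabolite_spec("m", ppm = 2.5, n_protons = 2, t1 = water3$t1,
                          t2 = water3$t2)
  rec <- quantify(am = 100, aw = 100, met = same, water = water3,
                  acq = acq_default)
  expect_equal(rec$cm_mM, water3$cw, tolerance = 1e-12)
  expect_equal(quantify(0, 100, same, water3, acq_default)$cm_mM, 0)
})

test_that("degenerate areas are rejected or clipped with flags", {
  expect_error(quantify(1, 0, mets3$NAA, water3, acq_default),
               class = "perispect_validation_error")
  rec <- quantify(-3, 100, mets3$NAA, water3, acq_default)
  expect_equal(rec$cm_mM, 0)
  expect_match(rec$qc_flags, "negative_area_clipped")
})

test_that("quantification is homogeneous of degree zero in joint amplitude", {
  v <- simulate_spectrum(ground_truth_voxel("PHE", c(NAA = 10)),
                         mets3, water3, acq_default)
  r1 <- quantify_spectra(v$suppressed, v$unsuppressed, mets3["NAA"],
                         water3, acq_default)
  s2 <- spectrum(2 * v$suppressed$values, v$suppressed$ppm)
  u2 <- spectrum(2 * v$unsuppressed$values, v$unsuppressed$ppm)
  r2 <- quantify_spectra(s2, u2, mets3["NAA"], water3, acq_default)
  expect_equal(r2$cm_mM, r1$cm_mM, tolerance = 1e-10)
  # doubling only the metabolite channel doubles the concentration
  r3 <- quantify_spectra(s2, v$unsuppressed, mets3["NAA"], water3, acq_default)
  expect_equal(r3$cm_mM, 2 * r1$cm_mM, tolerance = 1e-10)
})

test_that("noiseless round-trip recovery is within 0.5% for every metabolite", {
  truths <- c(NAA = 13.7, Cr = 9.43, Cho = 2.8)
  for (met in names(truths)) {
    v <- simulate_spectrum(
      ground_truth_voxel("CONTRA", stats::setNames(truths[[met]], met),
                         phase0 = 20, phase1 = 3),
      mets3, water3, acq_default)
    rec <- quantify_spectra(v$suppressed, v$unsuppressed, mets3[met],
                            water3, acq_default)
    expect_rel_equal(rec$cm_mM, truths[[met]], 0.005)
  }
})

test_that("recovery bias shrinks and precision grows with SNR", {
  stats_by_snr <- vapply(c(10, 20, 50), function(snr) {
    rs <- recovery_study(13.7, "NAA", n_reps = 40, snr = snr, seed = 33)
    c(mean = mean(rs$cm_hat), sd = stats::sd(rs$cm_hat))
  }, numeric(2))
  expect_true(all(diff(stats_by_snr["sd", ]) < 0))
  expect_lt(abs(stats_by_snr["mean", 3] / 13.7 - 1),
            abs(stats_by_snr["mean", 1] / 13.7 - 1) + 0.02)
})

test_that("grid quantification matches per-voxel calls and handles empty grids", {
  tm <- matrix(list(), 3, 3)
  for (i in 1:3) for (j in 1:3) {
    tm[[i, j]] <- ground_truth_voxel("CONTRA", c(NAA = 0))
  }
  tm[[1, 1]] <- ground_truth_voxel("PHE", c(NAA = 9.7, Cr = 3.62), snr = 40)
  tm[[3, 3]] <- ground_truth_voxel("CONTRA", c(NAA = 13.7, Cr = 9.43), snr = 40)
  g <- simulate_csi_grid(tm, mets3, water3, acq_small, seed = 21)
  lab <- matrix(NA_character_, 3, 3)
  lab[1, 1] <- "PHE"; lab[3, 3] <- "CONTRA"
  g$regions <- lab
  tab <- quantify_grid(g, mets3, water3, acq_small, regions_only = TRUE)
  expect_equal(nrow(tab), 2 * length(mets3))
  vx <- csi_voxel_at(g, 1, 1)
  direct <- quantify_spectra(vx$suppressed, vx$unsuppressed, mets3, water3,
                             acq_small, region = "PHE", voxel = c(1L, 1L))
  expect_equal(tab[tab$region == "PHE", ], direct, ignore_attr = TRUE)
  # single-voxel grid -> one record per metabolite
  tm1 <- matrix(list(ground_truth_voxel("PHE", c(NAA = 10))), 1, 1)
  g1 <- simulate_csi_grid(tm1, mets3, water3,
                          acquisition_params(n_points = 1024,
                                             grid_shape = c(1L, 1L)))
  expect_equal(nrow(quantify_grid(g1, mets3, water3)), length(mets3))
})
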