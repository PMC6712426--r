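# Complex trapezoidal integral of a spectrum over [lo, hi] ppm with the
# endpoints evaluated by linear interpolation, so the integration geometry
# does not depend on how the window falls on the discrete axis.
window_integral <- function(s, lo, hi) {
  idx <- which(s$ppm > lo & s$ppm < hi)
  x <- c(lo, s$ppm[idx], hi)
  re <- Re(s$values); im <- Im(s$values)
  yr <- c(stats::approx(s$ppm, re, lo)$y, re[idx],
          stats::approx(s$ppm, re, hi)$y)
  yi <- c(stats::approx(s$ppm, im, lo)$y, im[idx],
          stats::approx(s$ppm, im, hi)$y)
  complex(real = pracma::trapz(x, yr), imaginary = pracma::trapz(x, yi))
}

#' Automated zero/first-order phase correction
#'
#' Estimates the (phi0, phi1) phase error of a spectrum by fitting a
#' phase-constrained line model at the known peak positions and widths: the
#' observed spectrum is modelled as
#' `exp(i (phi0 + phi1 (ppm - pivot))) * sum_k a_k L_k(ppm)` with complex
#' Lorentzian lines `L_k` and real amplitudes `a_k`. For any candidate
#' (phi0, phi1) the amplitudes have a closed-form least-squares solution, so
#' the fit reduces to maximising a 2-parameter profile criterion (coarse
#' grid, then Nelder-Mead). The estimate is exact for noiseless Lorentzian
#' spectra, accounts for line overlap and for the phase gradient across
#' each line, and is used only for phasing - quantification remains
#' windowed integration.
#'
#' A single usable line (or `estimate_phi1 = FALSE`, e.g. for the
#' unsuppressed water spectrum) fixes phi1 = 0, since a lone narrow line
#' barely constrains the first-order term. The integrated magnitude of the
#' negative real-part lobes over `qc_region` after correction is reported
#' as a residual-phasing QC metric (`objective`).
#'
#' @param s a [spectrum()].
#' @param centers ppm positions of the lines used for estimation.
#' @param fwhm_ppm linewidth (FWHM, ppm) of each line, recycled; defaults
#'   to 5 Hz at 3 T.
#' @param fit_margin_ppm the fit uses axis points within this margin of the
#'   line centres.
#' @param estimate_phi1 estimate the first-order term? If `FALSE`, phi1 = 0.
#' @param pivot_ppm pivot of the first-order term (ppm).
#' @param qc_region ppm interval for the residual negative-lobe QC metric.
#' @return list of class `phase_fit`: `spectrum` (the corrected spectrum),
#'   `phi0`, `phi1` (the estimated applied error, degrees and degrees/ppm;
#'   `apply_phase(result$spectrum, phi0, phi1, pivot_ppm)` reproduces the
#'   input exactly), `converged`, `low_confidence` (TRUE when no line rises
#'   above the noise and the estimate should not be trusted), and
#'   `objective` (residual negative-lobe QC metric).
#' @export
#' @examples
#' pri <- load_priors()
#' v <- simulate_spectrum(
#'   ground_truth_voxel("PHE", c(NAA = 10), phase0 = 37, phase1 = 5),
#'   pri$metabolites, pri$water, acquisition_params(), seed = 1)
#' pc <- phase_correct(v$suppressed)
#' c(pc$phi0, pc$phi1)
phase_correct <- function(s, centers = c(2.01, 3.03, 3.19),
                          fwhm_ppm = 5 / 127.728, fit_margin_ppm = 0.5,
                          estimate_phi1 = TRUE, pivot_ppm = 4.7,
                          qc_region = range(centers) + c(-0.25, 0.25)) {
  stopifnot(inherits(s, "spectrum"))
  if (length(s$values) == 0L) {
    stopf("empty spectrum", class = "perispect_validation_error")
  }
  centers <- as.numeric(centers)
  fwhm_ppm <- rep_len(as.numeric(fwhm_ppm), length(centers))
  if (any(centers < min(s$ppm)) || any(centers > max(s$ppm))) {
    stopf("phase-estimation line centres outside the spectral axis",
          class = "perispect_validation_error")
  }

  # robust noise scale from the outermost eighths of the axis
  ntail <- max(16L, length(s$values) %/% 8L)
  tail_idx <- c(seq_len(ntail), length(s$values) - seq_len(ntail) + 1L)
  noise_scale <- stats::mad(Re(s$values[tail_idx]))
  dppm_step <- mean(diff(s$ppm))

  keep <- rep(FALSE, length(s$ppm))
  for (k in seq_along(centers)) {
    keep <- keep | (s$ppm >= centers[k] - fit_margin_ppm &
                      s$ppm <= centers[k] + fit_margin_ppm)
  }
  idx <- which(keep)
  v <- s$values[idx]
  dppm <- s$ppm[idx] - pivot_ppm
  M <- vapply(seq_along(centers), function(k) {
    gam <- fwhm_ppm[k] / 2
    (1 / pi) / complex(real = gam, imaginary = s$ppm[idx] - centers[k])
  }, complex(length(idx)))

  H <- Conj(t(M)) %*% M
  A <- Re(H)
  Ainv <- tryCatch(solve(A), error = function(e) {
    stopf("phase basis is singular (duplicate line centres?)",
          class = "perispect_validation_error")
  })

  # matched-filter amplitude per line, for the usability check only
  amp0 <- drop(Conj(t(M)) %*% v) / Re(diag(H))
  se <- if (is.finite(noise_scale) && noise_scale > 0) {
    noise_scale / sqrt(Re(diag(H)))
  } else rep(0, length(centers))
  usable <- Mod(amp0) > pmax(5 * se, 1e-3 * max(Mod(amp0)))
  low_confidence <- !any(usable)

  # profile criterion: for fixed phases the real amplitudes solve
  # A a = b(phi), and the residual norm is minimised by maximising
  # g(phi) = b' A^-1 b with b = Re(M^H (v e^{-i phi(ppm)}))
  g <- function(phi0, phi1) {
    y <- v * exp(-1i * (phi0 + phi1 * dppm) * pi / 180)
    b <- Re(drop(Conj(t(M)) %*% y))
    drop(t(b) %*% Ainv %*% b)
  }
  fit_phi1 <- estimate_phi1 && sum(usable) >= 2L && !low_confidence
  best <- c(0, 0); best_g <- -Inf
  for (p1 in (if (fit_phi1) seq(-24, 24, by = 6) else 0)) {
    for (p0 in seq(-180, 165, by = 15)) {
      gg <- g(p0, p1)
      if (gg > best_g) { best_g <- gg; best <- c(p0, p1) }
    }
  }
  if (fit_phi1) {
    opt <- stats::optim(best, function(p) -g(p[1], p[2]),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    best <- opt$par
  } else {
    opt <- stats::optimize(function(p0) -g(p0, 0),
                           interval = best[1] + c(-20, 20), tol = 1e-10)
    best <- c(opt$minimum, 0)
  }

  wrap180 <- function(a) ((a + 180) %% 360) - 180
  # an overall sign flip of the amplitudes is equivalent to a 180 deg
  # phase shift; disambiguate toward positive dominant amplitude
  y <- v * exp(-1i * (best[1] + best[2] * dppm) * pi / 180)
  a_hat <- drop(Ainv %*% Re(drop(Conj(t(M)) %*% y)))
  if (a_hat[which.max(abs(a_hat))] < 0) best[1] <- best[1] + 180

  phi0 <- wrap180(best[1])
  phi1 <- best[2]
  out <- apply_phase(s, -phi0, -phi1, pivot_ppm)
  qidx <- which(s$ppm >= qc_region[1] & s$ppm <= qc_region[2])
  objective <- sum(pmax(-Re(out$values[qidx]), 0)) * dppm_step
  structure(list(spectrum = out, phi0 = phi0, phi1 = phi1,
                 converged = TRUE, low_confidence = low_confidence,
                 objective = objective),
            class = "phase_fit")
}

#' Integrate a peak over a ppm window
#'
#' Trapezoidal integral of the real part over
#' `[center - half_width, center + half_width]` after subtracting a linear
#' baseline anchored at the window edges. The window endpoints and the
#' baseline anchors (the mean of `k_edge` interpolated samples at fixed
#' offsets inside each edge) are evaluated by linear interpolation at exact
#' ppm positions, so the integral geometry is identical for every peak
#' regardless of how its centre falls on the discrete axis; finite-window
#' attenuation then cancels in metabolite/water area ratios when linewidths
#' match.
#'
#' @param s a [spectrum()] (already phase-corrected).
#' @param center_ppm window centre (ppm).
#' @param half_width_ppm window half width (ppm); default 0.08 keeps the
#'   Cr (3.03) and Cho (3.19) windows disjoint.
#' @param k_edge number of edge samples averaged per baseline anchor.
#' @param metabolite optional label carried into the result.
#' @return list of class `peak_area`: `metabolite`, `area`, `window`,
#'   `baseline_slope`, `baseline_intercept`, `flags` (character vector).
#' @export
integrate_peak <- function(s, center_ppm, half_width_ppm = 0.08, k_edge = 5,
                           metabolite = NA_character_) {
  stopifnot(inherits(s, "spectrum"))
  assert_scalar_num(half_width_ppm, "half_width_ppm", positive = TRUE)
  lo <- center_ppm - half_width_ppm
  hi <- center_ppm + half_width_ppm
  if (lo < min(s$ppm) || hi > max(s$ppm)) {
    stopf("integration window [%.3f, %.3f] ppm outside the axis [%.3f, %.3f]",
          lo, hi, min(s$ppm), max(s$ppm), class = "perispect_validation_error")
  }
  re <- Re(s$values)
  idx <- which(s$ppm > lo & s$ppm < hi)
  dppm <- mean(diff(s$ppm))
  x <- c(lo, s$ppm[idx], hi)
  y <- c(stats::approx(s$ppm, re, lo)$y, re[idx],
         stats::approx(s$ppm, re, hi)$y)

  k <- max(1L, as.integer(k_edge))
  xs_left <- lo + (seq_len(k) - 1) * dppm
  xs_right <- hi - (seq_len(k) - 1) * dppm
  e1 <- mean(stats::approx(s$ppm, re, xs_left)$y)
  e2 <- mean(stats::approx(s$ppm, re, xs_right)$y)
  x1 <- mean(xs_left); x2 <- mean(xs_right)
  slope <- (e2 - e1) / (x2 - x1)
  intercept <- e1 - slope * x1
  area <- pracma::trapz(x, y - (intercept + slope * x))
  if (!is.finite(area)) {
    stopf("non-finite integral over [%.3f, %.3f] ppm", lo, hi,
          class = "perispect_validation_error")
  }
  structure(list(metabolite = metabolite, area = area, window = c(lo, hi),
                 baseline_slope = slope, baseline_intercept = intercept,
                 flags = character(0)),
            class = "peak_area")
}

#' Measure the unsuppressed water peak
#'
#' Phase-corrects the unsuppressed spectrum (zero-order only, over a window
#' around the water line) and integrates the water peak as
#' [integrate_peak()] at 4.7 ppm. Flags the result when the observed peak
#' maximum sits more than `half_width_ppm` away from the nominal centre.
#'
#' @param unsuppressed a [spectrum()] holding the water line.
#' @param center_ppm nominal water position (ppm).
#' @param half_width_ppm integration half width (ppm); keep equal to the
#'   metabolite window so finite-window attenuation cancels in area ratios.
#' @param k_edge baseline anchor width, as in [integrate_peak()].
#' @param phi1 known first-order phase (degrees/ppm, pivot at
#'   `center_ppm`), e.g. the estimate from the water-suppressed channel of
#'   the same voxel; a lone water line cannot identify it. Removed before
#'   the zero-order fit.
#' @return a `peak_area` with `metabolite = "water"`; `flags` may contain
#'   `"off_center"` or `"low_signal"`.
#' @export
measure_water <- function(unsuppressed, center_ppm = 4.7,
                          half_width_ppm = 0.08, k_edge = 5, phi1 = 0) {
  if (phi1 != 0) {
    unsuppressed <- apply_phase(unsuppressed, 0, -phi1,
                                pivot_ppm = center_ppm)
  }
  pc <- phase_correct(unsuppressed, centers = center_ppm,
                      estimate_phi1 = FALSE, pivot_ppm = center_ppm,
                      qc_region = center_ppm + c(-0.4, 0.4))
  s <- pc$spectrum
  pa <- integrate_peak(s, center_ppm, half_width_ppm, k_edge,
                       metabolite = "water")
  search <- which(s$ppm >= center_ppm - 0.6 & s$ppm <= center_ppm + 0.6)
  apex <- s$ppm[search][which.max(Re(s$values[search]))]
  flags <- character(0)
  if (pc$low_confidence) flags <- c(flags, "low_signal")
  if (abs(apex - center_ppm) > half_width_ppm) flags <- c(flags, "off_center")
  pa$flags <- flags
  pa
}

#' Water-signal ratio QC across regions and days
#'
#' Quality-control gate used before interpreting concentration changes: the
#' water area of each analysis voxel, expressed relative to the
#' contralesional voxel of the same day. A stable ratio over time indicates
#' that concentration changes are not driven by reference water-content
#' changes.
#'
#' @param grids named list of `csi_grid` objects, one per day; names are the
#'   day labels.
#' @param voxels named list mapping region ("PHE", "ATNE", "CONTRA") to a
#'   `c(row, col)` voxel index.
#' @param reference region used as the denominator.
#' @return data.frame with columns `day`, `region`, `aw`, `ratio`, `flag`.
#'   Ratios are `NA` (flagged) when the reference or target water area is
#'   not measurable.
#' @export
water_ratio_qc <- function(grids, voxels, reference = "CONTRA") {
  stopifnot(is.list(grids), length(names(grids)) == length(grids),
            reference %in% names(voxels))
  out <- list()
  for (day in names(grids)) {
    g <- grids[[day]]
    aw <- vapply(names(voxels), function(rg) {
      vx <- csi_voxel_at(g, voxels[[rg]][1], voxels[[rg]][2])
      pa <- measure_water(vx$unsuppressed)
      if (length(pa$flags) && "low_signal" %in% pa$flags) return(NA_real_)
      pa$area
    }, numeric(1))
    ref <- aw[[reference]]
    for (rg in names(voxels)) {
      bad <- !is.finite(aw[[rg]]) || !is.finite(ref) || ref <= 0
      out[[length(out) + 1L]] <- data.frame(
        day = day, region = rg, aw = aw[[rg]],
        ratio = if (bad) NA_real_ else aw[[rg]] / ref,
        flag = bad, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
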