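#' Ground-truth description of one CSI voxel
#'
#' Holds the true metabolite concentrations, the phase error applied by the
#' simulator and the signal-to-noise ratio. `snr` is defined per channel as
#' the ratio of that channel's dominant peak height (water for the
#' unsuppressed companion, the tallest metabolite line for the
#' water-suppressed spectrum) to the noise standard deviation of the real
#' part; `snr = Inf` gives noiseless spectra.
#'
#' @param region one of "PHE", "ATNE", "CONTRA".
#' @param concentrations named numeric vector of true concentrations (mM),
#'   names matching metabolite priors; all >= 0.
#' @param phase0 zero-order phase error (degrees).
#' @param phase1 first-order phase error (degrees/ppm).
#' @param snr per-channel peak signal-to-noise ratio (> 0, may be `Inf`).
#' @return an object of class `ground_truth_voxel`.
#' @export
#' @examples
#' ground_truth_voxel("CONTRA", c(NAA = 13.7, Cr = 9.43, Cho = 2.8), snr = 20)
ground_truth_voxel <- function(region = c("CONTRA", "PHE", "ATNE"),
                               concentrations, phase0 = 0, phase1 = 0,
                               snr = Inf) {
  region <- match.arg(region)
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stopf("concentrations must be a named vector",
          class = "perispect_validation_error")
  }
  if (any(concentrations < 0)) {
    stopf("concentrations must be >= 0 (got %s)",
          paste(concentrations, collapse = ", "),
          class = "perispect_validation_error")
  }
  if (!(is.numeric(snr) && length(snr) == 1L && snr > 0)) {
    stopf("snr must be a single value > 0", class = "perispect_validation_error")
  }
  assert_scalar_num(phase0, "phase0")
  assert_scalar_num(phase1, "phase1")
  structure(list(region = region, concentrations = concentrations,
                 phase0 = phase0, phase1 = phase1, snr = snr),
            class = "ground_truth_voxel")
}

# Complex Lorentzian line: absorption in the real part (integral = `area`),
# dispersion in the imaginary part, as produced by Fourier transform of an
# exponentially decaying FID. fwhm is given in Hz and converted to ppm via
# the field strength.
lorentzian_line <- function(ppm, center_ppm, area, fwhm_hz, field_ppm_hz) {
  gamma <- (fwhm_hz / field_ppm_hz) / 2
  (area / pi) / complex(real = gamma, imaginary = ppm - center_ppm)
}

lorentzian_height <- function(area, fwhm_hz, field_ppm_hz) {
  gamma <- (fwhm_hz / field_ppm_hz) / 2
  area / (pi * gamma)
}

#' Simulate a water-suppressed/unsuppressed spectrum pair for one voxel
#'
#' Forward model of the quantification equation: each metabolite contributes
#' an absorption Lorentzian whose integrated area is
#' `Am = Cm * Aw * Nm (1-exp(-TR/T1m)) exp(-TE/T2m) /
#'  (Cw * Nw (1-exp(-TR/T1w)) exp(-TE/T2w))`,
#' i.e. the relaxation-corrected water-referencing relation inverted, so
#' quantification recovers the truth exactly in the noiseless limit. The
#' unsuppressed companion holds the water line with known area `aw_scale`.
#' Zero/first-order phase (pivot at water) is applied to both channels,
#' then independent circular complex Gaussian noise at the voxel's `snr`.
#'
#' @param truth a [ground_truth_voxel()].
#' @param mets named list of [metabolite_spec()] priors.
#' @param water a [water_reference()].
#' @param acq an [acquisition_params()].
#' @param seed integer seed for the noise draw (`NULL` = use current RNG).
#' @param aw_scale injected water-peak area (arbitrary units).
#' @return list of class `csi_voxel` with elements `suppressed`,
#'   `unsuppressed` ([spectrum()] objects), `truth`, `am` (named injected
#'   metabolite areas), `aw`, and the per-channel noise SDs.
#' @export
#' @examples
#' pri <- load_priors()
#' v <- simulate_spectrum(
#'   ground_truth_voxel("CONTRA", c(NAA = 13.7)),
#'   pri$metabolites, pri$water, acquisition_params(), seed = 1)
#' v$am
simulate_spectrum <- function(truth, mets, water, acq, seed = NULL,
                              aw_scale = 1000) {
  stopifnot(inherits(truth, "ground_truth_voxel"),
            inherits(water, "water_reference"),
            inherits(acq, "acq_params"))
  ppm <- ppm_axis(acq, water_ppm = water$ppm)
  cm <- truth$concentrations
  unknown <- setdiff(names(cm), names(mets))
  if (length(unknown)) {
    stopf("no prior for metabolite(s): %s", paste(unknown, collapse = ", "),
          class = "perispect_validation_error")
  }
  for (nm in names(cm)) {
    p <- mets[[nm]]$ppm
    if (p <= min(ppm) || p >= max(ppm)) {
      stopf("metabolite %s at %.2f ppm lies outside the spectral axis [%.2f, %.2f]",
            nm, p, min(ppm), max(ppm), class = "perispect_validation_error")
    }
  }

  am <- vapply(names(cm), function(nm) {
    cm[[nm]] * aw_scale / (relaxation_factor(mets[[nm]], water, acq) * water$cw)
  }, numeric(1))
  names(am) <- names(cm)

  sup <- complex(length(ppm))
  heights <- numeric(0)
  for (nm in names(cm)) {
    m <- mets[[nm]]
    sup <- sup + lorentzian_line(ppm, m$ppm, am[[nm]], m$linewidth,
                                 acq$field_ppm_hz)
    heights <- c(heights, lorentzian_height(am[[nm]], m$linewidth,
                                            acq$field_ppm_hz))
  }
  unsup <- lorentzian_line(ppm, water$ppm, aw_scale, water$linewidth,
                           acq$field_ppm_hz)
  h_water <- lorentzian_height(aw_scale, water$linewidth, acq$field_ppm_hz)
  h_met <- if (length(heights) && max(heights) > 0) max(heights) else h_water

  sup <- spectrum(sup, ppm)
  unsup <- spectrum(unsup, ppm)
  sup <- apply_phase(sup, truth$phase0, truth$phase1, pivot_ppm = water$ppm)
  unsup <- apply_phase(unsup, truth$phase0, truth$phase1, pivot_ppm = water$ppm)

  sigma_sup <- if (is.finite(truth$snr)) h_met / truth$snr else 0
  sigma_unsup <- if (is.finite(truth$snr)) h_water / truth$snr else 0
  n <- length(ppm)
  noisy <- with_seed(seed, {
    list(s = complex(real = stats::rnorm(n, 0, sigma_sup),
                     imaginary = stats::rnorm(n, 0, sigma_sup)),
         u = complex(real = stats::rnorm(n, 0, sigma_unsup),
                     imaginary = stats::rnorm(n, 0, sigma_unsup)))
  })
  if (sigma_sup > 0) sup$values <- sup$values + noisy$s
  if (sigma_unsup > 0) unsup$values <- unsup$values + noisy$u

  structure(list(suppressed = sup, unsuppressed = unsup, truth = truth,
                 am = am, aw = aw_scale,
                 sigma = c(suppressed = sigma_sup, unsuppressed = sigma_unsup),
                 acq = acq),
            class = "csi_voxel")
}

#' Simulate a full CSI grid
#'
#' One spectrum pair per voxel of the CSI matrix; region labels from the
#' truth map are preserved in the grid metadata. Per-voxel noise streams are
#' derived deterministically from `seed`.
#'
#' @param truth_map list of [ground_truth_voxel()] with a `dim` attribute
#'   matching `acq$grid_shape` (row-major list-matrix), e.g. as returned by
#'   `matrix(list(...), nrow, ncol)`.
#' @inheritParams simulate_spectrum
#' @return object of class `csi_grid`: complex arrays `suppressed` and
#'   `unsuppressed` of dim `(n_points, rows, cols)`, `ppm`, a character
#'   matrix `regions`, the truth map, and the acquisition parameters.
#' @export
simulate_csi_grid <- function(truth_map, mets, water, acq, seed = NULL,
                              aw_scale = 1000) {
  dm <- dim(truth_map)
  if (is.null(dm) || length(dm) != 2L || !all(dm == acq$grid_shape)) {
    stopf("truth_map shape (%s) does not match acq$grid_shape (%s)",
          paste(dm, collapse = "x"), paste(acq$grid_shape, collapse = "x"),
          class = "perispect_validation_error")
  }
  nr <- dm[1]; nc <- dm[2]; np <- acq$n_points
  sup <- array(complex(real = 0), dim = c(np, nr, nc))
  uns <- array(complex(real = 0), dim = c(np, nr, nc))
  regions <- matrix(NA_character_, nr, nc)
  truths <- truth_map
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vseed <- if (is.null(base_seed)) NULL else
        (base_seed + 7919L * ((i - 1L) * nc + j)) %% .Machine$integer.max
      v <- simulate_spectrum(truth_map[[i, j]], mets, water, acq,
                             seed = vseed, aw_scale = aw_scale)
      sup[, i, j] <- v$suppressed$values
      uns[, i, j] <- v$unsuppressed$values
      regions[i, j] <- truth_map[[i, j]]$region
    }
  }
  structure(list(suppressed = sup, unsuppressed = uns,
                 ppm = ppm_axis(acq, water_ppm = water$ppm),
                 regions = regions, truth = truths, acq = acq,
                 aw_scale = aw_scale),
            class = "csi_grid")
}

#' Extract one voxel of a CSI grid as a spectrum pair
#'
#' @param grid a `csi_grid`.
#' @param row,col 1-based voxel indices.
#' @return list with `suppressed` and `unsuppressed` [spectrum()] objects
#'   and the voxel's `region` label.
#' @export
csi_voxel_at <- function(grid, row, col) {
  stopifnot(inherits(grid, "csi_grid"))
  dm <- dim(grid$suppressed)
  if (row < 1 || row > dm[2] || col < 1 || col > dm[3]) {
    stopf("voxel (%d, %d) outside the %dx%d grid", row, col, dm[2], dm[3],
          class = "perispect_validation_error")
  }
  list(suppressed = spectrum(grid$suppressed[, row, col], grid$ppm),
       unsuppressed = spectrum(grid$unsuppressed[, row, col], grid$ppm),
       region = grid$regions[row, col])
}

#' Write / read a CSI grid container
#'
#' Serialises a `csi_grid` to a single JSON container holding the
#' `suppressed` and `unsuppressed` datasets (as real/imaginary arrays), the
#' `ppm_axis`, the region-label matrix and the acquisition parameters.
#'
#' @param grid a `csi_grid`.
#' @param path output file path (conventionally `.csi.json`).
#' @return `write_csi`: the path, invisibly. `read_csi`: a `csi_grid`.
#' @export
write_csi <- function(grid, path) {
  stopifnot(inherits(grid, "csi_grid"))
  obj <- list(
    format = "perispect-csi",
    version = 1L,
    dims = dim(grid$suppressed),
    suppressed = list(re = as.numeric(Re(grid$suppressed)),
                      im = as.numeric(Im(grid$suppressed))),
    unsuppressed = list(re = as.numeric(Re(grid$unsuppressed)),
                        im = as.numeric(Im(grid$unsuppressed))),
    ppm_axis = grid$ppm,
    regions = list(values = as.character(grid$regions), dim = dim(grid$regions)),
    acquisition = unclass(grid$acq),
    aw_scale = grid$aw_scale,
    truth = lapply(grid$truth, function(t) {
      t <- unclass(t)
      t$concentrations <- as.list(t$concentrations)  # keep names in JSON
      t
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_csi
#' @export
read_csi <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(o$format, "perispect-csi")) {
    stopf("%s is not a perispect CSI container", path,
          class = "perispect_validation_error")
  }
  dims <- as.integer(o$dims)
  acq <- acquisition_params(tr = o$acquisition$tr, te = o$acquisition$te,
                            bandwidth = o$acquisition$bandwidth,
                            n_points = o$acquisition$n_points,
                            field_ppm_hz = o$acquisition$field_ppm_hz,
                            grid_shape = o$acquisition$grid_shape,
                            voxel_size = o$acquisition$voxel_size)
  truth <- lapply(o$truth, function(t) {
    conc <- unlist(t$concentrations)
    ground_truth_voxel(t$region, conc, as.numeric(t$phase0),
                       as.numeric(t$phase1),
                       if (is.null(t$snr)) Inf else as.numeric(t$snr))
  })
  dim(truth) <- dims[2:3]
  structure(list(
    suppressed = array(complex(real = o$suppressed$re, imaginary = o$suppressed$im),
                       dim = dims),
    unsuppressed = array(complex(real = o$unsuppressed$re, imaginary = o$unsuppressed$im),
                         dim = dims),
    ppm = as.numeric(o$ppm_axis),
    regions = matrix(o$regions$values, o$regions$dim[1], o$regions$dim[2]),
    truth = truth, acq = acq, aw_scale = o$aw_scale),
    class = "csi_grid")
}
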