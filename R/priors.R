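#' Acquisition parameters for a CSI experiment
#'
#' Container for the sequence parameters that drive both the forward
#' simulator and the relaxation correction: repetition time, echo time,
#' spectral bandwidth, number of spectral points, the field-dependent
#' Hz-per-ppm conversion, the CSI matrix size and the voxel dimensions.
#'
#' @param tr repetition time (ms).
#' @param te echo time (ms); must satisfy `tr > te > 0`.
#' @param bandwidth spectral width (Hz).
#' @param n_points samples per spectrum (>= 256).
#' @param field_ppm_hz Hz per ppm; 127.728 at 3 T.
#' @param grid_shape integer vector (rows, cols) of the CSI matrix.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @return an object of class `acq_params`.
#' @export
#' @examples
#' acq <- acquisition_params()
#' range(ppm_axis(acq))
acquisition_params <- function(tr = 2000, te = 144, bandwidth = 2000,
                               n_points = 2048, field_ppm_hz = 127.728,
                               grid_shape = c(9L, 9L),
                               voxel_size = c(15, 15, 15)) {
  assert_scalar_num(tr, "tr", positive = TRUE)
  assert_scalar_num(te, "te", positive = TRUE)
  if (tr <= te) {
    stopf("require tr > te > 0 (got tr = %g, te = %g)", tr, te,
          class = "perispect_validation_error")
  }
  assert_scalar_num(bandwidth, "bandwidth", positive = TRUE)
  assert_scalar_num(n_points, "n_points", positive = TRUE)
  if (n_points < 256) {
    stopf("n_points must be >= 256 (got %d)", n_points,
          class = "perispect_validation_error")
  }
  assert_scalar_num(field_ppm_hz, "field_ppm_hz", positive = TRUE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    stopf("grid_shape must be two positive integers",
          class = "perispect_validation_error")
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stopf("voxel_size must be three positive edge lengths (mm)",
          class = "perispect_validation_error")
  }
  structure(list(tr = tr, te = te, bandwidth = bandwidth,
                 n_points = as.integer(n_points),
                 field_ppm_hz = field_ppm_hz, grid_shape = grid_shape,
                 voxel_size = voxel_size),
            class = "acq_params")
}

#' Chemical-shift axis of an acquisition
#'
#' Ascending ppm axis centred on water (4.7 ppm). Display is conventionally
#' reversed; internally everything is stored ascending.
#'
#' @param acq an [acquisition_params()] object.
#' @param water_ppm chemical shift of water (ppm).
#' @return numeric vector of length `acq$n_points`.
#' @export
ppm_axis <- function(acq, water_ppm = 4.7) {
  n <- acq$n_points
  hz <- (seq_len(n) - 1 - n / 2) * (acq$bandwidth / n)
  water_ppm + hz / acq$field_ppm_hz
}

#' Metabolite prior (resonance and relaxation parameters)
#'
#' @param name metabolite label, e.g. "NAA".
#' @param ppm chemical-shift centre in (0, 10) ppm.
#' @param n_protons number of contributing protons (>= 1).
#' @param t1,t2 longitudinal/transverse relaxation times (ms), `t1 > t2 > 0`.
#' @param linewidth full width at half maximum (Hz).
#' @return an object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, ppm, n_protons, t1, t2, linewidth = 5) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_scalar_num(ppm, "ppm")
  if (ppm <= 0 || ppm >= 10) {
    stopf("ppm must lie in (0, 10) (got %g)", ppm,
          class = "perispect_validation_error")
  }
  assert_scalar_num(n_protons, "n_protons", positive = TRUE)
  if (n_protons < 1) {
    stopf("n_protons must be >= 1", class = "perispect_validation_error")
  }
  assert_scalar_num(t1, "t1", positive = TRUE)
  assert_scalar_num(t2, "t2", positive = TRUE)
  if (t1 <= t2) {
    stopf("require t1 > t2 > 0 for %s (got t1 = %g, t2 = %g)", name, t1, t2,
          class = "perispect_validation_error")
  }
  assert_scalar_num(linewidth, "linewidth", positive = TRUE)
  structure(list(name = name, ppm = ppm, n_protons = n_protons,
                 t1 = t1, t2 = t2, linewidth = linewidth),
            class = "metabolite_spec")
}

#' Water reference parameters
#'
#' The unsuppressed tissue-water line used as the internal concentration
#' reference. `cw` defaults to pure-water molarity (55510 mM) scaled by a
#' tissue water fraction; both the fraction and the relaxation times are
#' site-replaceable stand-ins, not measured values.
#'
#' @param ppm water chemical shift (ppm).
#' @param n_protons protons per water molecule (2).
#' @param t1,t2 water relaxation times (ms).
#' @param cw reference water concentration in tissue (mM); default
#'   `55510 * water_fraction`.
#' @param water_fraction tissue water fraction used for the default `cw`.
#' @param linewidth rendered water linewidth (Hz), used by the simulator.
#' @return an object of class `water_reference`.
#' @export
water_reference <- function(ppm = 4.7, n_protons = 2, t1 = 1200, t2 = 80,
                            water_fraction = 0.71,
                            cw = 55510 * water_fraction, linewidth = 5) {
  if (n_protons != 2) {
    stopf("water has n_protons = 2 (got %g)", n_protons,
          class = "perispect_validation_error")
  }
  assert_scalar_num(cw, "cw", positive = TRUE)
  assert_scalar_num(t1, "t1", positive = TRUE)
  assert_scalar_num(t2, "t2", positive = TRUE)
  if (t1 <= t2) {
    stopf("require t1 > t2 > 0 for water", class = "perispect_validation_error")
  }
  assert_scalar_num(linewidth, "linewidth", positive = TRUE)
  structure(list(name = "water", ppm = ppm, n_protons = n_protons,
                 t1 = t1, t2 = t2, cw = cw, linewidth = linewidth),
            class = "water_reference")
}

#' Load metabolite/water priors from a YAML table
#'
#' Reads a versioned priors file (see `inst/extdata/priors-3t.yaml` for the
#' shipped 3 T defaults) into [metabolite_spec()] and [water_reference()]
#' objects. The shipped relaxation times and water concentration are
#' literature-informed stand-ins and are meant to be replaced per site.
#'
#' @param path YAML file; defaults to the shipped 3 T table.
#' @return list with elements `metabolites` (named list of
#'   `metabolite_spec`), `water` (`water_reference`) and `field_ppm_hz`.
#' @export
load_priors <- function(path = system.file("extdata", "priors-3t.yaml",
                                           package = "perispect")) {
  y <- yaml::read_yaml(path)
  mets <- lapply(y$metabolites, function(m) {
    metabolite_spec(m$name, m$ppm, m$n_protons, m$t1_ms, m$t2_ms,
                    m$linewidth_hz %||% 5)
  })
  names(mets) <- vapply(mets, `[[`, character(1), "name")
  wat <- water_reference(ppm = y$water$ppm, n_protons = y$water$n_protons,
                         t1 = y$water$t1_ms, t2 = y$water$t2_ms,
                         cw = y$water$cw_mM,
                         linewidth = y$water$linewidth_hz %||% 5)
  list(metabolites = mets, water = wat,
       field_ppm_hz = y$field_ppm_hz %||% 127.728)
}

#' Shipped default priors
#'
#' Convenience accessors for the 3 T priors table shipped with the package.
#'
#' @return `default_metabolites()`: named list of [metabolite_spec()] for
#'   NAA, Cr and Cho; `default_water()`: a [water_reference()].
#' @export
default_metabolites <- function() load_priors()$metabolites

#' @rdname default_metabolites
#' @export
default_water <- function() load_priors()$water
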