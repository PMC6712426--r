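#' Relaxation/proton correction factor for water referencing
#'
#' The dimensionless factor
#' `Nw (1 - exp(-TR/T1w)) exp(-TE/T2w) / (Nm (1 - exp(-TR/T1m)) exp(-TE/T2m))`
#' that converts a metabolite/water area ratio into a concentration ratio.
#' In the fully relaxed, zero-echo limit (TE -> 0, TR >> T1) it reduces to
#' the proton-count ratio `Nw / Nm`.
#'
#' @param met a [metabolite_spec()].
#' @param water a [water_reference()].
#' @param acq an [acquisition_params()] (supplies TR and TE, ms).
#' @return strictly positive scalar.
#' @export
#' @examples
#' pri <- load_priors()
#' relaxation_factor(pri$metabolites$NAA, pri$water, acquisition_params())
relaxation_factor <- function(met, water, acq) {
  stopifnot(inherits(met, "metabolite_spec"),
            inherits(water, "water_reference"),
            inherits(acq, "acq_params"))
  for (x in list(met$t1, met$t2, water$t1, water$t2)) {
    if (!is.finite(x) || x <= 0) {
      stopf("relaxation times must be positive",
            class = "perispect_validation_error")
    }
  }
  num <- water$n_protons * (1 - exp(-acq$tr / water$t1)) * exp(-acq$te / water$t2)
  den <- met$n_protons * (1 - exp(-acq$tr / met$t1)) * exp(-acq$te / met$t2)
  num / den
}

#' Absolute concentration from metabolite and water peak areas
#'
#' Water-referenced quantification with relaxation correction:
#' `Cm = (Am / Aw) * relaxation_factor * Cw`, in mM. A negative metabolite
#' area (integration noise) is clipped to zero and flagged rather than
#' propagated as a negative concentration.
#'
#' @param am metabolite `peak_area` (or a bare numeric area).
#' @param aw water `peak_area` (or numeric); its area must be > 0.
#' @param met a [metabolite_spec()].
#' @param water a [water_reference()].
#' @param acq an [acquisition_params()].
#' @param region optional region label carried into the record.
#' @param voxel optional `c(row, col)` carried into the record.
#' @return one-row data.frame (a `concentration_record`) with columns
#'   `voxel_row`, `voxel_col`, `region`, `metabolite`, `am`, `aw`,
#'   `correction`, `cm_mM`, `qc_flags`.
#' @export
quantify <- function(am, aw, met, water, acq, region = NA_character_,
                     voxel = c(NA_integer_, NA_integer_)) {
  am_area <- if (inherits(am, "peak_area")) am$area else as.numeric(am)
  aw_area <- if (inherits(aw, "peak_area")) aw$area else as.numeric(aw)
  flags <- character(0)
  if (inherits(am, "peak_area")) flags <- c(flags, am$flags)
  if (inherits(aw, "peak_area")) flags <- c(flags, aw$flags)
  if (!is.finite(aw_area) || aw_area <= 0) {
    stopf("water reference area must be > 0 (got %g)", aw_area,
          class = "perispect_validation_error")
  }
  corr <- relaxation_factor(met, water, acq)
  if (am_area < 0) {
    flags <- c(flags, "negative_area_clipped")
    am_area_eff <- 0
  } else {
    am_area_eff <- am_area
  }
  cm <- (am_area_eff / aw_area) * corr * water$cw
  data.frame(voxel_row = voxel[1], voxel_col = voxel[2], region = region,
             metabolite = met$name, am = am_area, aw = aw_area,
             correction = corr, cm_mM = cm,
             qc_flags = paste(unique(flags), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Quantify one spectrum pair
#'
#' Full per-voxel processing chain: phase-correct the water-suppressed
#' spectrum (metabolite-region objective), phase-correct and integrate the
#' unsuppressed water line, integrate each metabolite window, and apply the
#' water-referenced concentration equation.
#'
#' @param suppressed,unsuppressed [spectrum()] objects for one voxel.
#' @param mets named list of [metabolite_spec()].
#' @param water a [water_reference()].
#' @param acq an [acquisition_params()].
#' @param half_width_ppm integration half width (ppm), shared by metabolite
#'   and water windows.
#' @param region,voxel labels carried into the records.
#' @return data.frame with one `concentration_record` row per metabolite.
#' @export
quantify_spectra <- function(suppressed, unsuppressed, mets, water, acq,
                             half_width_ppm = 0.08, region = NA_character_,
                             voxel = c(NA_integer_, NA_integer_)) {
  pc <- phase_correct(suppressed, pivot_ppm = water$ppm)
  aw <- measure_water(unsuppressed, center_ppm = water$ppm,
                      half_width_ppm = half_width_ppm, phi1 = pc$phi1)
  rows <- lapply(mets, function(m) {
    pa <- integrate_peak(pc$spectrum, m$ppm, half_width_ppm,
                         metabolite = m$name)
    if (pc$low_confidence) pa$flags <- c(pa$flags, "low_phase_confidence")
    quantify(pa, aw, m, water, acq, region = region, voxel = voxel)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Quantify every voxel of a CSI grid
#'
#' Applies [quantify_spectra()] voxel-by-voxel; each voxel is referenced to
#' its own unsuppressed water line (internal referencing). Region labels
#' from the grid metadata identify the PHE/ATNE/CONTRA analysis voxels.
#'
#' @param grid a `csi_grid`.
#' @inheritParams quantify_spectra
#' @param regions_only if `TRUE`, only voxels with a non-`NA` region label
#'   are quantified (the three analysis voxels in a labelled grid).
#' @return data.frame of concentration records.
#' @export
quantify_grid <- function(grid, mets, water, acq = grid$acq,
                          half_width_ppm = 0.08, regions_only = FALSE) {
  stopifnot(inherits(grid, "csi_grid"))
  dm <- dim(grid$suppressed)
  out <- list()
  for (i in seq_len(dm[2])) {
    for (j in seq_len(dm[3])) {
      rg <- grid$regions[i, j]
      if (regions_only && is.na(rg)) next
      vx <- csi_voxel_at(grid, i, j)
      out[[length(out) + 1L]] <- quantify_spectra(
        vx$suppressed, vx$unsuppressed, mets, water, acq,
        half_width_ppm = half_width_ppm, region = rg, voxel = c(i, j))
    }
  }
  if (!length(out)) {
    return(data.frame(voxel_row = integer(0), voxel_col = integer(0),
                      region = character(0), metabolite = character(0),
                      am = numeric(0), aw = numeric(0),
                      correction = numeric(0), cm_mM = numeric(0),
                      qc_flags = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
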