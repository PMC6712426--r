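#' Spectrum object
#'
#' A complex spectrum on an ascending ppm axis.
#'
#' @param values complex (or numeric) intensities.
#' @param ppm ascending chemical-shift axis, same length as `values`.
#' @param meta optional list of acquisition metadata.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(values, ppm, meta = list()) {
  if (length(values) != length(ppm)) {
    stopf("values and ppm must have equal length",
          class = "perispect_validation_error")
  }
  if (length(ppm) < 2L || any(diff(ppm) <= 0)) {
    stopf("ppm axis must be strictly increasing",
          class = "perispect_validation_error")
  }
  structure(list(values = as.complex(values), ppm = as.numeric(ppm),
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.2f-%.2f ppm, max |S| = %.4g\n",
              length(x$values), min(x$ppm), max(x$ppm), max(Mod(x$values))))
  invisible(x)
}

#' Apply zero- and first-order phase to a spectrum
#'
#' Rotates the spectrum by `phi0 + phi1 * (ppm - pivot)` degrees. The pivot
#' is the water resonance by default, so a first-order term leaves the water
#' line essentially unrotated.
#'
#' @param s a [spectrum()].
#' @param phi0 zero-order phase (degrees).
#' @param phi1 first-order phase (degrees/ppm).
#' @param pivot_ppm pivot of the first-order term (ppm).
#' @return a phased [spectrum()].
#' @export
apply_phase <- function(s, phi0, phi1 = 0, pivot_ppm = 4.7) {
  phi <- (phi0 + phi1 * (s$ppm - pivot_ppm)) * pi / 180
  spectrum(s$values * exp(1i * phi), s$ppm, s$meta)
}
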