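#' Spectrometer context
#'
#' Describes the static field and receiver convention under which spin systems
#' are simulated: the field strength, the proton Larmor (reference) frequency
#' and the chemical shift at the receiver centre. All rotating-frame offsets in
#' the package are computed as \code{(center_ppm - shift_ppm) * f0}, so a
#' resonance downfield of the carrier appears at a negative offset and the ppm
#' axis runs in the usual descending MRS display order.
#'
#' @param field_t Static field strength in tesla. Default 3.
#' @param center_ppm Chemical shift (ppm) of the receiver centre / carrier.
#'   Default 4.65 (water).
#' @param reference_frequency_mhz Proton Larmor frequency in MHz. If `NULL`
#'   (default) it is derived as `42.5775 MHz/T * field_t` (127.73 MHz at 3 T).
#'
#' @return An object of class `spectrometer_context` with fields `field_t`,
#'   `f0_mhz` and `center_ppm`.
#' @export
#' @examples
#' ctx <- spectrometer_context()
#' ctx$f0_mhz  # ~127.73 at 3 T
spectrometer_context <- function(field_t = 3, center_ppm = 4.65,
                                 reference_frequency_mhz = NULL) {
  stopifnot(is.numeric(field_t), length(field_t) == 1L, field_t > 0)
  gamma_mhz_per_t <- 42.5775
  f0 <- if (is.null(reference_frequency_mhz)) {
    gamma_mhz_per_t * field_t
  } else {
    reference_frequency_mhz
  }
  if (abs(f0 - gamma_mhz_per_t * field_t) > 0.05 * f0) {
    stop("reference_frequency_mhz is inconsistent with field_t ",
         "(expected about ", round(gamma_mhz_per_t * field_t, 2), " MHz)")
  }
  structure(
    list(field_t = field_t, f0_mhz = f0, center_ppm = center_ppm),
    class = "spectrometer_context"
  )
}

#' @export
print.spectrometer_context <- function(x, ...) {
  cat(sprintf("<spectrometer_context> %.2f T, f0 = %.3f MHz, carrier at %.2f ppm\n",
              x$field_t, x$f0_mhz, x$center_ppm))
  invisible(x)
}

# Offset (Hz) of a resonance relative to the receiver centre, in the sign
# convention used throughout: positive offset for shifts upfield of the carrier.
ppm_to_offset_hz <- function(ppm, ctx) {
  (ctx$center_ppm - ppm) * ctx$f0_mhz
}

offset_hz_to_ppm <- function(hz, ctx) {
  ctx$center_ppm - hz / ctx$f0_mhz
}
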