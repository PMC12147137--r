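#' Spectrometer configuration
#'
#' Field strength and 19F frequency constants used to convert chemical-shift
#' offsets (ppm) and saturation amplitudes (uT) into angular frequencies.
#'
#' @param b0_field Static magnetic flux density in tesla.
#' @param larmor_freq_19F 19F Larmor frequency in MHz.  The default, 470.4 MHz,
#'   is the observed 19F frequency at 11.7 T; it must agree with
#'   `b0_field * gamma_19F / 2pi` to within 1%.
#' @param gamma_19F 19F gyromagnetic ratio in rad s^-1 T^-1.
#'
#' @return An object of class `spectrometer_config`.
#' @export
#' @examples
#' cfg <- spectrometer_config()
#' ppm_to_rad_per_s(-28.6, cfg)
spectrometer_config <- function(b0_field = 11.7,
                                larmor_freq_19F = 470.4,
                                gamma_19F = 2 * pi * 40.078e6) {
  stopifnot(
    is.numeric(b0_field), length(b0_field) == 1L, is.finite(b0_field),
    is.numeric(larmor_freq_19F), length(larmor_freq_19F) == 1L,
    is.numeric(gamma_19F), length(gamma_19F) == 1L
  )
  if (b0_field <= 0 || larmor_freq_19F <= 0 || gamma_19F <= 0)
    stop("all spectrometer constants must be strictly positive")
  nominal_mhz <- b0_field * gamma_19F / (2 * pi) / 1e6
  if (abs(larmor_freq_19F - nominal_mhz) / nominal_mhz > 0.01)
    stop(sprintf(
      "larmor_freq_19F (%.1f MHz) inconsistent with b0_field * gamma / 2pi (%.1f MHz)",
      larmor_freq_19F, nominal_mhz
    ))
  structure(
    list(b0_field = b0_field, larmor_freq_19F = larmor_freq_19F,
         gamma_19F = gamma_19F),
    class = "spectrometer_config"
  )
}

#' Convert a chemical-shift offset from ppm to angular frequency
#'
#' Offsets are relative to the free-guest resonance at 0 ppm; positive ppm is
#' downfield.  ppm times the Larmor frequency in MHz gives Hz.
#'
#' @param offset_ppm Offset(s) in ppm (vectorized).
#' @param cfg A [spectrometer_config()].
#' @return Angular frequency in rad s^-1.
#' @export
ppm_to_rad_per_s <- function(offset_ppm, cfg = spectrometer_config()) {
  stopifnot(inherits(cfg, "spectrometer_config"), is.numeric(offset_ppm))
  offset_ppm * cfg$larmor_freq_19F * 2 * pi
}

#' Convert a saturation amplitude from microtesla to nutation frequency
#'
#' @param b1_uT Saturation amplitude(s) in uT (vectorized, non-negative).
#' @param cfg A [spectrometer_config()].
#' @return Nutation frequency omega_1 = gamma * B1 in rad s^-1.
#' @export
b1_to_rad_per_s <- function(b1_uT, cfg = spectrometer_config()) {
  stopifnot(inherits(cfg, "spectrometer_config"), is.numeric(b1_uT))
  if (any(b1_uT < 0)) stop("b1 must be non-negative")
  cfg$gamma_19F * b1_uT * 1e-6
}

#' @export
print.spectrometer_config <- function(x, ...) {
  cat(sprintf("<spectrometer_config> B0 = %.2f T, 19F Larmor = %.1f MHz\n",
              x$b0_field, x$larmor_freq_19F))
  invisible(x)
}
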