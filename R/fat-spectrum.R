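#' Reduced gyromagnetic ratio of the proton
#'
#' \eqn{\bar\gamma = 42.5775} MHz/T, used to convert chemical-shift offsets in
#' ppm to absolute frequencies in Hz at a given field strength
#' (\eqn{f\,[\mathrm{Hz}] = \bar\gamma\,[\mathrm{MHz/T}] \cdot B_0\,[\mathrm{T}]
#' \cdot \delta\,[\mathrm{ppm}]}).
#'
#' @export
GAMMA_BAR_MHZ_PER_T <- 42.5775

#' Multi-peak fat resonance spectrum
#'
#' Describes the fat signal as a set of spectral peaks at chemical-shift
#' offsets relative to water, with relative amplitudes that are normalized to
#' sum to one. An additive temperature shift (applied to every offset) models
#' the temperature dependence of the fat-water frequency difference; for
#' room-temperature phantom work the conventional correction is +0.11 ppm.
#'
#' @param offsets_ppm Chemical-shift offsets of the fat peaks relative to
#'   water, in ppm. Negative for the main methylene peak (fat precesses more
#'   slowly than water under the sign convention used throughout the package).
#' @param amplitudes Relative peak amplitudes. Normalized internally so they
#'   sum to exactly 1.
#' @param temp_shift_ppm Additive shift applied to all offsets (ppm).
#'   Default 0 (body temperature / in vivo convention).
#' @return An object of class `fam_spectrum`.
#' @seealso [default_fat_spectrum()], [fat_phasor()]
#' @export
fat_spectrum <- function(offsets_ppm, amplitudes, temp_shift_ppm = 0) {
  if (length(offsets_ppm) < 1L || length(offsets_ppm) != length(amplitudes)) {
    stop("offsets_ppm and amplitudes must have equal length >= 1", call. = FALSE)
  }
  if (any(!is.finite(offsets_ppm)) || any(!is.finite(amplitudes))) {
    stop("spectrum values must be finite", call. = FALSE)
  }
  if (any(amplitudes < 0) || sum(amplitudes) <= 0) {
    stop("amplitudes must be nonnegative with positive sum", call. = FALSE)
  }
  structure(
    list(
      offsets_ppm = as.numeric(offsets_ppm),
      amplitudes = as.numeric(amplitudes) / sum(amplitudes),
      temp_shift_ppm = as.numeric(temp_shift_ppm)
    ),
    class = "fam_spectrum"
  )
}

#' Default six-peak liver fat spectrum
#'
#' The widely used six-peak triglyceride model (methyl, methylene, allylic,
#' alpha-carboxyl/diallylic, glycerol and olefinic resonances). Amplitudes are
#' normalized to sum to one.
#'
#' @param phantom If `TRUE`, apply the +0.11 ppm room-temperature shift to all
#'   offsets (phantom convention); if `FALSE` (default), no shift (in vivo).
#' @return A [fat_spectrum()].
#' @export
default_fat_spectrum <- function(phantom = FALSE) {
  fat_spectrum(
    offsets_ppm = c(-3.80, -3.40, -2.60, -1.94, -0.39, 0.60),
    amplitudes  = c(0.087, 0.693, 0.128, 0.004, 0.039, 0.048),
    temp_shift_ppm = if (isTRUE(phantom)) 0.11 else 0
  )
}

#' @export
print.fam_spectrum <- function(x, ...) {
  cat("<fam_spectrum> ", length(x$offsets_ppm), " peaks, temp shift ",
      x$temp_shift_ppm, " ppm\n", sep = "")
  print(tibble::tibble(offset_ppm = x$offsets_ppm, amplitude = x$amplitudes))
  invisible(x)
}

#' Peak frequencies of a fat spectrum at a given field strength
#'
#' @param spectrum A [fat_spectrum()].
#' @param b0_t Field strength in tesla.
#' @return Numeric vector of peak frequencies in Hz (relative to water).
#' @export
fat_peak_freqs_hz <- function(spectrum, b0_t) {
  stopifnot(inherits(spectrum, "fam_spectrum"), b0_t > 0)
  GAMMA_BAR_MHZ_PER_T * b0_t * (spectrum$offsets_ppm + spectrum$temp_shift_ppm)
}

#' Complex fat phasor at given echo times
#'
#' The unit-bounded complex weight of the fat signal relative to water,
#' \eqn{c(TE) = \sum_p a_p \exp(i 2\pi f_p TE)} with
#' \eqn{f_p = \bar\gamma B_0 (\delta_p + \Delta\delta_{temp})}. At `TE = 0`
#' the phasor is exactly 1 because the amplitudes sum to one.
#'
#' @inheritParams fat_peak_freqs_hz
#' @param te_ms Echo time(s) in milliseconds (vectorized), `>= 0`.
#' @return Complex vector, one value per echo time, with modulus `<= 1`.
#' @export
fat_phasor <- function(spectrum, te_ms, b0_t) {
  stopifnot(inherits(spectrum, "fam_spectrum"))
  if (any(te_ms < 0)) stop("te_ms must be nonnegative", call. = FALSE)
  if (b0_t <= 0) stop("b0_t must be positive", call. = FALSE)
  f_hz <- fat_peak_freqs_hz(spectrum, b0_t)
  te_s <- te_ms / 1000
  vapply(
    te_s,
    function(t) sum(spectrum$amplitudes * exp(1i * 2 * pi * f_hz * t)),
    complex(1)
  )
}
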