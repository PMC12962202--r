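#' Single-voxel tissue description
#'
#' Bundles the parameters of the standard confounder-corrected
#' chemical-shift-encoded (CSE) signal model for one voxel. The water and fat
#' proton densities are `W = m0 * (1 - pdff)` and `F = m0 * pdff`, and
#' `PDFF = F / (W + F)`.
#'
#' @param m0 Equilibrium proton density (arbitrary units), `>= 0`.
#' @param pdff Proton-density fat fraction, in `[0, 1]`.
#' @param t1_water_ms,t1_fat_ms Longitudinal relaxation times of water and fat
#'   protons (ms), `> 0`.
#' @param r2star_s Common effective transverse decay rate R2* (1/s), `>= 0`.
#' @param psi_hz B0 field offset (Hz); positive psi produces phase
#'   `+2*pi*psi*TE` under the package's sign convention.
#' @return An object of class `fam_voxel`.
#' @export
tissue_voxel <- function(m0 = 1, pdff = 0, t1_water_ms = 1000,
                         t1_fat_ms = 300, r2star_s = 0, psi_hz = 0) {
  if (pdff < 0 || pdff > 1) stop("pdff must lie in [0, 1]", call. = FALSE)
  if (t1_water_ms <= 0 || t1_fat_ms <= 0) stop("T1 values must be positive", call. = FALSE)
  if (r2star_s < 0) stop("r2star_s must be nonnegative", call. = FALSE)
  if (m0 < 0) stop("m0 must be nonnegative", call. = FALSE)
  structure(
    list(m0 = m0, pdff = pdff, t1_water_ms = t1_water_ms,
         t1_fat_ms = t1_fat_ms, r2star_s = r2star_s, psi_hz = psi_hz),
    class = "fam_voxel"
  )
}

#' Multi-echo CSE voxel signal
#'
#' Evaluates the standard confounder-corrected model
#' \deqn{s(TE_n) = (W + F\,c_n)\,e^{-R_2^* TE_n}\,e^{i 2\pi \psi TE_n},}
#' where \eqn{c_n} is the multi-peak fat phasor at \eqn{TE_n}.
#'
#' @param voxel A [tissue_voxel()].
#' @param spectrum A [fat_spectrum()].
#' @param tes_ms Strictly increasing, nonnegative echo times (ms).
#' @param b0_t Field strength (T).
#' @return Complex vector of length `length(tes_ms)`.
#' @export
cse_signal <- function(voxel, spectrum, tes_ms, b0_t) {
  stopifnot(inherits(voxel, "fam_voxel"))
  if (any(tes_ms < 0) || any(diff(tes_ms) <= 0)) {
    stop("tes_ms must be nonnegative and strictly increasing", call. = FALSE)
  }
  w <- voxel$m0 * (1 - voxel$pdff)
  f <- voxel$m0 * voxel$pdff
  cn <- fat_phasor(spectrum, tes_ms, b0_t)
  te_s <- tes_ms / 1000
  (w + f * cn) * exp((-voxel$r2star_s + 1i * 2 * pi * voxel$psi_hz) * te_s)
}

#' Spoiled gradient-echo steady-state signal
#'
#' The classical SPGR steady-state law
#' \deqn{S/M_0 = \sin\alpha \, (1 - E_1) / (1 - E_1 \cos\alpha), \quad
#'   E_1 = e^{-TR/T_1},}
#' i.e. the signal a constant-flip-angle acquisition converges to after many
#' excitations, as a fraction of the equilibrium magnetization.
#'
#' @param alpha_deg Flip angle in degrees, in `(0, 90]`.
#' @param tr_ms Repetition time (ms), `> 0`.
#' @param t1_ms Longitudinal relaxation time (ms), `> 0`.
#' @return Relative signal in `(0, 1]` (vectorized over any argument).
#' @export
spgr_steady_state <- function(alpha_deg, tr_ms, t1_ms) {
  if (any(alpha_deg <= 0) || any(alpha_deg > 90)) {
    stop("alpha_deg must lie in (0, 90]", call. = FALSE)
  }
  if (any(tr_ms <= 0) || any(t1_ms <= 0)) stop("tr_ms and t1_ms must be positive", call. = FALSE)
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Apparent PDFF under constant-flip steady-state acquisition
#'
#' The T1-related bias mechanism of steady-state CSE-MRI: because fat
#' (shorter T1) is less saturated than water at a given flip angle, the
#' apparent fat fraction of a steady-state acquisition is
#' \deqn{PDFF_{app} = \frac{F\,g_f}{F\,g_f + W\,g_w},}
#' with \eqn{g} the [spgr_steady_state()] factor at each species' T1. For
#' `T1_fat < T1_water` the apparent PDFF overestimates the true PDFF; the bias
#' vanishes as the flip angle approaches zero or when the two T1s are equal.
#'
#' @param true_pdff True proton-density fat fraction in `[0, 1]`.
#' @inheritParams spgr_steady_state
#' @param t1_water_ms,t1_fat_ms Water and fat T1 (ms).
#' @return Apparent PDFF (fraction in `[0, 1]`).
#' @examples
#' # a 3 degree, TR 6.4 ms steady-state acquisition reads a true 30% fat
#' # fraction as about 31.7% for typical liver T1 values
#' 100 * apparent_pdff_steady_state(0.30, 3, 6.4, t1_water_ms = 809, t1_fat_ms = 382)
#' @export
apparent_pdff_steady_state <- function(true_pdff, alpha_deg, tr_ms,
                                       t1_water_ms, t1_fat_ms) {
  if (any(true_pdff < 0) || any(true_pdff > 1)) {
    stop("true_pdff must lie in [0, 1]", call. = FALSE)
  }
  gf <- spgr_steady_state(alpha_deg, tr_ms, t1_fat_ms)
  gw <- spgr_steady_state(alpha_deg, tr_ms, t1_water_ms)
  f <- true_pdff * gf
  w <- (1 - true_pdff) * gw
  f / (f + w)
}
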