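#' Acquisition parameter set
#'
#' Full description of a 2D multi-echo spoiled-gradient-echo protocol:
#' field strength, repetition time, monopolar echo train, matrix and FOV.
#' Flyback (monopolar) readout timing is abstracted: echo times are taken at
#' face value and are not required to fit inside TR.
#'
#' @param b0_t Field strength in tesla used for ppm-to-Hz conversion.
#' @param tr_ms Repetition time (ms).
#' @param te1_ms First echo time (ms).
#' @param dte_ms Echo spacing (ms).
#' @param n_echoes Number of echoes, `>= 2`.
#' @param matrix Integer vector `c(nx, ny)`; `ny` is the phase-encode
#'   dimension (one excitation per PE line). Both `>= 8`.
#' @param fov_cm Field of view `c(x, y)` in cm.
#' @param slice_thickness_mm Slice thickness (mm).
#' @param n_slices Number of slices (sequential 2D).
#' @param readout `"monopolar"` (flyback) is the only supported readout.
#' @param flip_mode `"fam"` (variable flip schedule) or `"constant"`.
#' @param alpha_deg Constant flip angle in degrees (used when
#'   `flip_mode = "constant"`).
#' @param b0_label Optional nominal field label (e.g. a 2.89 T system declared
#'   "3T"); purely descriptive.
#' @return An object of class `fam_params`.
#' @export
acq_params <- function(b0_t, tr_ms, te1_ms, dte_ms, n_echoes,
                       matrix = c(144L, 144L), fov_cm = c(44, 44),
                       slice_thickness_mm = 8, n_slices = 32,
                       readout = "monopolar",
                       flip_mode = c("fam", "constant"),
                       alpha_deg = NULL, b0_label = NULL) {
  flip_mode <- match.arg(flip_mode)
  if (n_echoes < 2) stop("n_echoes must be >= 2", call. = FALSE)
  if (any(c(b0_t, tr_ms, te1_ms, dte_ms, slice_thickness_mm) <= 0)) {
    stop("all times and the field strength must be positive", call. = FALSE)
  }
  matrix <- as.integer(matrix)
  if (length(matrix) != 2L || any(matrix < 8L)) {
    stop("matrix must be two integers >= 8", call. = FALSE)
  }
  if (readout != "monopolar") stop("only monopolar (flyback) readouts are supported", call. = FALSE)
  if (flip_mode == "constant" && is.null(alpha_deg)) {
    stop("alpha_deg is required for constant flip mode", call. = FALSE)
  }
  structure(
    list(b0_t = b0_t, tr_ms = tr_ms, te1_ms = te1_ms, dte_ms = dte_ms,
         n_echoes = as.integer(n_echoes), matrix = matrix,
         fov_cm = as.numeric(fov_cm), slice_thickness_mm = slice_thickness_mm,
         n_slices = as.integer(n_slices), readout = readout,
         flip_mode = flip_mode, alpha_deg = alpha_deg,
         b0_label = b0_label %||% paste0(b0_t, "T")),
    class = "fam_params"
  )
}

#' @export
print.fam_params <- function(x, ...) {
  cat("<fam_params> ", x$b0_label, "  TR ", x$tr_ms, " ms, ",
      x$n_echoes, " echoes (TE1 ", x$te1_ms, ", dTE ", x$dte_ms, " ms), matrix ",
      x$matrix[1], "x", x$matrix[2], ", flip mode ", x$flip_mode, "\n", sep = "")
  invisible(x)
}

#' Echo times of a protocol
#'
#' @param params A [acq_params()] object.
#' @return Numeric vector `te1 + (0:(n-1)) * dte` (ms).
#' @export
echo_times_ms <- function(params) {
  stopifnot(inherits(params, "fam_params"))
  params$te1_ms + (seq_len(params$n_echoes) - 1) * params$dte_ms
}

#' Named protocol presets
#'
#' Loads one of the protocol presets shipped with the package
#' (`"0.55T"`, `"1.5T"`, `"3T"` variable-flip 2D protocols, and
#' `"3T-3D-CSE"`, the constant 3-degree steady-state comparator).
#'
#' @param name Preset name.
#' @param file Optional path to a YAML protocol file to read instead of the
#'   packaged presets.
#' @return A [acq_params()] object.
#' @export
protocol_preset <- function(name, file = NULL) {
  file <- file %||% system.file("extdata", "protocols.yaml", package = "famfat")
  presets <- yaml::read_yaml(file)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  acq_params(
    b0_t = p$b0_t, tr_ms = p$tr_ms, te1_ms = p$te1_ms, dte_ms = p$dte_ms,
    n_echoes = p$n_echoes, matrix = unlist(p$matrix),
    fov_cm = unlist(p$fov_cm), slice_thickness_mm = p$slice_thickness_mm,
    n_slices = p$n_slices, readout = p$readout, flip_mode = p$flip_mode,
    alpha_deg = p$alpha_deg, b0_label = p$b0_label
  )
}

#' Centric phase-encode ordering
#'
#' Acquisition order that visits the DC line first (index `floor(ny/2) + 1`,
#' 1-based) and then alternates outward, positive offset before negative at
#' equal distance, clipping at the array bounds.
#'
#' @param ny Number of phase-encode lines, `>= 1`.
#' @return Integer permutation of `1:ny`; element `j` is the PE line acquired
#'   at excitation `j`.
#' @export
centric_order <- function(ny) {
  ny <- as.integer(ny)
  if (is.na(ny) || ny < 1L) stop("ny must be >= 1", call. = FALSE)
  dc <- ny %/% 2L + 1L
  offsets <- c(0L, as.vector(rbind(seq_len(ny), -seq_len(ny))))
  cand <- dc + offsets
  cand[cand >= 1L & cand <= ny][seq_len(ny)]
}

#' Per-excitation flip-angle schedule
#'
#' @param alphas_deg Flip angles in degrees, one per excitation, in
#'   `(0, cap_deg]`.
#' @param pe_order Permutation mapping excitation index to PE line (1-based);
#'   defaults to [centric_order()]. Its first element must be the DC line.
#' @param cap_deg Maximum allowed flip angle (degrees).
#' @return An object of class `fam_schedule`.
#' @export
flip_schedule <- function(alphas_deg, pe_order = centric_order(length(alphas_deg)),
                          cap_deg = 90) {
  ny <- length(alphas_deg)
  if (ny < 1L) stop("schedule must have length >= 1", call. = FALSE)
  if (any(alphas_deg <= 0) || any(alphas_deg > cap_deg)) {
    stop("flip angles must lie in (0, cap_deg]", call. = FALSE)
  }
  if (!identical(sort(as.integer(pe_order)), seq_len(ny))) {
    stop("pe_order must be a permutation of 1:ny", call. = FALSE)
  }
  if (pe_order[1] != ny %/% 2L + 1L) {
    stop("pe_order must start at the DC line (centric)", call. = FALSE)
  }
  structure(
    list(alphas_deg = as.numeric(alphas_deg), pe_order = as.integer(pe_order),
         cap_deg = cap_deg),
    class = "fam_schedule"
  )
}

#' @export
print.fam_schedule <- function(x, ...) {
  cat("<fam_schedule> ", length(x$alphas_deg), " excitations, flip ",
      round(min(x$alphas_deg), 2), "-", round(max(x$alphas_deg), 2),
      " deg (cap ", x$cap_deg, ")\n", sep = "")
  invisible(x)
}

#' Transient signal of a variable-flip spoiled-gradient-echo train
#'
#' Longitudinal-magnetization recursion starting from equilibrium:
#' \deqn{S_j = M_z(j) \sin\alpha_j, \quad
#'   M_z(j{+}1) = M_z(j)\cos\alpha_j \, E_1 + M_0 (1 - E_1),}
#' with \eqn{M_z(1) = M_0} and \eqn{E_1 = e^{-TR/T_1}}. Perfect spoiling of
#' transverse magnetization is assumed. The first-excitation signal
#' \eqn{M_0 \sin\alpha_1} is independent of T1 — the mechanism by which a
#' centric-ordered acquisition escapes steady-state T1 bias at the k-space
#' center.
#'
#' @param schedule A [flip_schedule()], or a numeric vector of per-excitation
#'   flip angles in degrees, or a single constant flip angle (then `n_pulses`
#'   is required).
#' @param tr_ms Repetition time (ms).
#' @param t1_ms Longitudinal relaxation time (ms).
#' @param m0 Equilibrium magnetization (default 1).
#' @param n_pulses Train length when `schedule` is a single angle.
#' @return Numeric vector of per-excitation signals \eqn{S_j}.
#' @export
transient_signal <- function(schedule, tr_ms, t1_ms, m0 = 1, n_pulses = NULL) {
  alphas <- if (inherits(schedule, "fam_schedule")) {
    schedule$alphas_deg
  } else if (length(schedule) == 1L && !is.null(n_pulses)) {
    rep(as.numeric(schedule), n_pulses)
  } else {
    as.numeric(schedule)
  }
  if (length(alphas) < 1L) stop("schedule must have length >= 1", call. = FALSE)
  if (tr_ms <= 0 || t1_ms <= 0) stop("tr_ms and t1_ms must be positive", call. = FALSE)
  a <- alphas * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  s <- numeric(length(a))
  mz <- m0
  for (j in seq_along(a)) {
    s[j] <- mz * sin(a[j])
    mz <- mz * cos(a[j]) * e1 + m0 * (1 - e1)
  }
  s
}

#' Per-line k-space weighting induced by a flip schedule
#'
#' Maps per-excitation transient signals onto phase-encode lines:
#' `weights[pe_order[j]] = S_j / m0`. Starting from equilibrium, the DC weight
#' is `sin(alpha_1)` for every T1, while outer lines carry the T1-dependent
#' transient decay. `mode = "steady_state"` instead applies the converged
#' constant-flip weighting (flat across k-space) using the schedule's first
#' flip angle.
#'
#' @inheritParams transient_signal
#' @param params A [acq_params()]; its `matrix[2]` must equal the schedule
#'   length.
#' @param mode `"transient"` (FAM) or `"steady_state"` (constant-flip).
#' @return An object of class `fam_kweights`: relative amplitude per PE line
#'   (`weights`), the T1 it was computed for, and the PE order.
#' @export
kspace_weighting <- function(schedule, params, t1_ms,
                             mode = c("transient", "steady_state")) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "fam_schedule"), inherits(params, "fam_params"))
  ny <- params$matrix[2]
  if (length(schedule$alphas_deg) != ny) {
    stop("schedule length must equal the number of PE lines", call. = FALSE)
  }
  w <- numeric(ny)
  if (mode == "transient") {
    s <- transient_signal(schedule, params$tr_ms, t1_ms, m0 = 1)
    w[schedule$pe_order] <- s
  } else {
    w[] <- spgr_steady_state(schedule$alphas_deg[1], params$tr_ms, t1_ms)
  }
  structure(list(weights = w, t1_ms = t1_ms, pe_order = schedule$pe_order,
                 mode = mode),
            class = "fam_kweights")
}

#' Point-spread-function metrics of a k-space weighting
#'
#' Computes the phase-encode-direction PSF as the densely zero-padded inverse
#' DFT of the per-line weights and summarizes it by the full-width at
#' half-maximum relative to the uniform (box) weighting of the same length,
#' and by the largest sidelobe as a fraction of the peak.
#'
#' @param weighting A [kspace_weighting()] result or a bare numeric vector of
#'   per-line weights (length `>= 8`).
#' @param pad Zero-padding factor for dense PSF sampling (default 16).
#' @return List with `fwhm_broadening` (ratio `>= 1` up to discretization)
#'   and `max_sidelobe` (fraction of the main-lobe peak).
#' @export
psf_metrics <- function(weighting, pad = 16L) {
  w <- if (inherits(weighting, "fam_kweights")) weighting$weights else as.numeric(weighting)
  ny <- length(w)
  if (ny < 8L) stop("need at least 8 PE lines", call. = FALSE)
  if (sum(w != 0) < 2L) stop("degenerate weighting: fewer than 2 nonzero lines", call. = FALSE)
  list(
    fwhm_broadening = psf_fwhm(w, pad) / psf_fwhm(rep(1, ny), pad),
    max_sidelobe = psf_sidelobe(w, pad)
  )
}

# dense |PSF| by centered zero-padding; x axis in voxel units
psf_profile <- function(w, pad) {
  ny <- length(w)
  n <- as.integer(pad) * ny
  kbig <- complex(n)
  lo <- (n - ny) %/% 2L
  kbig[lo + seq_len(ny)] <- w
  # shift so DC (line ny%/%2+1, i.e. centered) sits at bin 1
  dcbin <- lo + ny %/% 2L + 1L
  kbig <- kbig[c(dcbin:n, seq_len(dcbin - 1L))]
  psf <- Mod(stats::fft(kbig, inverse = TRUE))
  # recentre the spatial axis
  psf <- psf[c((n %/% 2L + 1L):n, seq_len(n %/% 2L))]
  list(x = ((seq_len(n) - 1) - n %/% 2) * ny / n, y = psf)
}

psf_fwhm <- function(w, pad) {
  p <- psf_profile(w, pad)
  pk <- which.max(p$y)
  half <- p$y[pk] / 2
  right <- pk
  while (right < length(p$y) && p$y[right + 1] > half) right <- right + 1L
  left <- pk
  while (left > 1L && p$y[left - 1] > half) left <- left - 1L
  if (right == length(p$y) || left == 1L) stop("PSF main lobe not resolved", call. = FALSE)
  interp <- function(i1, i2) {
    p$x[i1] + (half - p$y[i1]) / (p$y[i2] - p$y[i1]) * (p$x[i2] - p$x[i1])
  }
  interp(right, right + 1L) - interp(left, left - 1L)
}

psf_sidelobe <- function(w, pad) {
  p <- psf_profile(w, pad)
  pk <- which.max(p$y)
  right <- pk
  while (right < length(p$y) && p$y[right + 1] <= p$y[right]) right <- right + 1L
  left <- pk
  while (left > 1L && p$y[left - 1] <= p$y[left]) left <- left - 1L
  outside <- p$y[-(left:right)]
  if (!length(outside)) return(0)
  max(outside) / p$y[pk]
}

#' Target signal profile for FAM schedule design
#'
#' Per-excitation relative signal the schedule solver will track: a flat top
#' at `sin(alpha1)` near the k-space center, then an exponential decay toward
#' the Ernst-level floor — the maximum signal sustainable indefinitely at the
#' reference T1, \eqn{\sqrt{(1-E_1)/(1+E_1)}}. A flat top preserves
#' resolution; decaying toward a sustainable floor keeps the required flip
#' angles below the cap and apodizes the outer k-space smoothly.
#'
#' @param ny Train length (number of PE lines).
#' @param tr_ms,t1_ms Repetition time and reference T1 (ms).
#' @param alpha1_deg First flip angle (degrees); sets the flat-top level.
#' @param flat_frac Fraction of the train held at the flat top.
#' @param decay_frac Fraction of the train over which the target decays from
#'   the flat-top level to the floor.
#' @return Numeric positive, non-increasing vector of length `ny`.
#' @export
fam_target <- function(ny, tr_ms, t1_ms, alpha1_deg = 6,
                       flat_frac = 0.15, decay_frac = 0.35) {
  s0 <- sin(alpha1_deg * pi / 180)
  e1 <- exp(-tr_ms / t1_ms)
  floor_level <- sqrt((1 - e1) / (1 + e1))
  if (floor_level >= s0) return(rep(s0, ny))
  nf <- max(1L, round(flat_frac * ny))
  tau <- (decay_frac * ny) / log(s0 / floor_level)
  j <- seq_len(ny)
  pmax(floor_level, ifelse(j <= nf, s0, s0 * exp(-(j - nf) / tau)))
}

#' Solve a FAM flip-angle schedule by target tracking
#'
#' Inverts the transient-signal recursion exactly: at each excitation the flip
#' angle is chosen so the signal meets the target profile at the reference T1,
#' \eqn{\alpha_j = \arcsin(t_j / M_z(j))}, capped at `cap_deg` whenever the
#' required angle is infeasible (the signal then falls below target —
#' "capped" excitations). The solved schedule is validated post hoc: PSF
#' metrics of the induced weighting and the maximum discrepancy of
#' DC-normalized weightings between a short and a long reference T1 are
#' attached as the `design` attribute.
#'
#' @param params A [acq_params()].
#' @param t1_refs Named or unnamed numeric pair `c(t1_short, t1_long)` in ms;
#'   the schedule is solved at the long T1 (slowest recovery) and its
#'   weighting checked at both.
#' @param target Target profile: numeric vector of length `ny`, or `NULL` to
#'   use [fam_target()] defaults.
#' @param cap_deg Flip-angle cap (degrees).
#' @param alpha1_deg,flat_frac,decay_frac Passed to [fam_target()] when
#'   `target` is `NULL`.
#' @return A [flip_schedule()] with attribute `design` (target, achieved
#'   signal, capped flags, PSF metrics at both reference T1s, cross-T1
#'   weighting discrepancy).
#' @export
solve_fam_schedule <- function(params, t1_refs = c(t1_short = 300, t1_long = 1400),
                               target = NULL, cap_deg = 90, alpha1_deg = 6,
                               flat_frac = 0.15, decay_frac = 0.35) {
  stopifnot(inherits(params, "fam_params"))
  ny <- params$matrix[2]
  t1_refs <- sort(as.numeric(t1_refs))
  t1_solve <- t1_refs[2]
  if (is.null(target)) {
    target <- fam_target(ny, params$tr_ms, t1_solve, alpha1_deg = alpha1_deg,
                         flat_frac = flat_frac, decay_frac = decay_frac)
  }
  if (length(target) != ny || any(target <= 0)) {
    stop("target must be a positive vector with one entry per PE line", call. = FALSE)
  }
  if (any(diff(target) > 1e-12)) {
    stop("target profile must be non-increasing from the k-space center outward",
         call. = FALSE)
  }
  cap_rad <- cap_deg * pi / 180
  if (target[1] > sin(cap_rad) + 1e-12) {
    stop("infeasible target: first excitation requires a flip above the cap",
         call. = FALSE)
  }
  e1 <- exp(-params$tr_ms / t1_solve)
  alphas <- numeric(ny)
  capped <- logical(ny)
  achieved <- numeric(ny)
  mz <- 1
  for (j in seq_len(ny)) {
    req <- target[j] / mz
    if (req >= sin(cap_rad)) {
      alphas[j] <- cap_deg
      capped[j] <- TRUE
    } else {
      alphas[j] <- asin(req) * 180 / pi
    }
    a <- alphas[j] * pi / 180
    achieved[j] <- mz * sin(a)
    mz <- mz * cos(a) * e1 + (1 - e1)
  }
  sched <- flip_schedule(alphas, cap_deg = cap_deg)
  w_short <- kspace_weighting(sched, params, t1_refs[1])
  w_long <- kspace_weighting(sched, params, t1_refs[2])
  discrepancy <- max(abs(w_short$weights / w_short$weights[sched$pe_order[1]] -
                           w_long$weights / w_long$weights[sched$pe_order[1]]))
  attr(sched, "design") <- list(
    target = target, achieved = achieved, capped = capped,
    t1_refs = t1_refs,
    psf_short = psf_metrics(w_short), psf_long = psf_metrics(w_long),
    cross_t1_discrepancy = discrepancy
  )
  sched
}

#' Cramér–Rao lower bound on PDFF variance for a magnitude fit
#'
#' Lower bound on the variance of the PDFF estimate from the
#' three-parameter magnitude model `|W + F c(TE)| exp(-R2* TE)` with known
#' Gaussian noise SD, via the Fisher information of (W, F, R2*) and the delta
#' method for `PDFF = F/(W+F)`. Scales as `noise_sd^2`.
#'
#' @param params A [acq_params()] (supplies the echo train and B0).
#' @param voxel A [tissue_voxel()] at which the bound is evaluated.
#' @param spectrum A [fat_spectrum()].
#' @param noise_sd Gaussian noise SD per magnitude sample (image units).
#' @return Variance of the PDFF estimate (fraction squared); `Inf` with a
#'   warning when the information matrix is numerically singular (e.g. all
#'   echoes at the same effective fat–water phase).
#' @export
crlb_pdff_variance <- function(params, voxel, spectrum, noise_sd) {
  stopifnot(inherits(params, "fam_params"), inherits(voxel, "fam_voxel"))
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  tes <- echo_times_ms(params)
  if (params$n_echoes < 3L) stop("need at least 3 echoes for (W, F, R2*)", call. = FALSE)
  cn <- fat_phasor(spectrum, tes, params$b0_t)
  te_s <- tes / 1000
  w <- voxel$m0 * (1 - voxel$pdff)
  f <- voxel$m0 * voxel$pdff
  z <- w + f * cn
  az <- Mod(z)
  if (any(az == 0)) {
    warning("signal null at an echo; information matrix singular")
    return(Inf)
  }
  dec <- exp(-voxel$r2star_s * te_s)
  jac <- cbind(
    Re(z) / az * dec,                # d|s|/dW
    Re(z * Conj(cn)) / az * dec,     # d|s|/dF
    -te_s * az * dec                 # d|s|/dR2*
  )
  jtj <- crossprod(jac)
  if (rcond(jtj) < 1e-12) {
    warning("near-singular information matrix: echoes carry no fat-water contrast")
    return(Inf)
  }
  g <- c(-f, w, 0) / (w + f)^2
  noise_sd^2 * drop(t(g) %*% solve(jtj, g))
}

#' Sequence timing
#'
#' Per-slice temporal footprint of a sequential 2D acquisition (one
#' excitation per PE line, `TR * Ny`) and the total time over all slices.
#' The total uses the per-slice value rounded to one decimal, matching the
#' convention of reported protocol tables.
#'
#' @param params A [acq_params()].
#' @return A tibble with `per_slice_s` (exact), `per_slice_rounded_s` and
#'   `total_s`.
#' @export
sequence_timing <- function(params) {
  stopifnot(inherits(params, "fam_params"))
  per_slice <- params$tr_ms * params$matrix[2] / 1000
  tibble::tibble(
    per_slice_s = per_slice,
    per_slice_rounded_s = round(per_slice, 1),
    total_s = round(per_slice, 1) * params$n_slices
  )
}
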