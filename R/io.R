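#' Write an echo series as NIfTI volumes with a JSON sidecar
#'
#' Real and imaginary parts are written as two 3D NIfTI volumes
#' (`<prefix>_real.nii.gz`, `<prefix>_imag.nii.gz`, echoes along the third
#' dimension) plus `<prefix>.json` carrying echo times, protocol, noise
#' level and seed.
#'
#' @param series A [echo_series()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the sidecar path.
#' @export
write_echo_series <- function(series, dir, prefix = "echoes") {
  stopifnot(inherits(series, "fam_echoes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$images[[1]])
  ne <- length(series$images)
  re <- array(0, c(d, ne)); im <- array(0, c(d, ne))
  for (n in seq_len(ne)) {
    re[, , n] <- Re(series$images[[n]])
    im[, , n] <- Im(series$images[[n]])
  }
  vx <- series$params$fov_cm * 10 / series$params$matrix   # mm
  RNifti::writeNifti(RNifti::asNifti(re, pixdim = c(vx, 1)),
                     file.path(dir, paste0(prefix, "_real.nii.gz")))
  RNifti::writeNifti(RNifti::asNifti(im, pixdim = c(vx, 1)),
                     file.path(dir, paste0(prefix, "_imag.nii.gz")))
  side <- list(
    tes_ms = series$tes_ms, noise_sd = series$noise_sd,
    seed = series$seed, mode = series$mode,
    params = unclass(series$params)
  )
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an echo series written by [write_echo_series()]
#'
#' @param dir Directory containing the files.
#' @param prefix File name prefix used at write time.
#' @return A [echo_series()].
#' @export
read_echo_series <- function(dir, prefix = "echoes") {
  side <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  re <- as.array(RNifti::readNifti(file.path(dir, paste0(prefix, "_real.nii.gz"))))
  im <- as.array(RNifti::readNifti(file.path(dir, paste0(prefix, "_imag.nii.gz"))))
  ne <- dim(re)[3]
  images <- lapply(seq_len(ne), function(n) {
    matrix(complex(real = re[, , n], imaginary = im[, , n]), dim(re)[1], dim(re)[2])
  })
  p <- side$params
  params <- acq_params(
    b0_t = p$b0_t, tr_ms = p$tr_ms, te1_ms = p$te1_ms, dte_ms = p$dte_ms,
    n_echoes = p$n_echoes, matrix = p$matrix, fov_cm = p$fov_cm,
    slice_thickness_mm = p$slice_thickness_mm, n_slices = p$n_slices,
    readout = p$readout, flip_mode = p$flip_mode, alpha_deg = p$alpha_deg,
    b0_label = p$b0_label
  )
  echo_series(images, side$tes_ms, params,
              noise_sd = side$noise_sd %||% 0,
              seed = side$seed, mode = side$mode)
}

#' Write fitted parameter maps as NIfTI plus provenance JSON
#'
#' @param fit A `fam_fit`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param provenance Optional named list merged into the JSON sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_fit_maps <- function(fit, dir, prefix = "fit", provenance = list()) {
  stopifnot(inherits(fit, "fam_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- list(pdff = fit$pdff, r2star = fit$r2star_s, fieldmap = fit$psi_hz,
               water = fit$water, fat = fit$fat, residual = fit$residual)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    m[is.na(m)] <- 0
    RNifti::writeNifti(RNifti::asNifti(m),
                       file.path(dir, paste0(prefix, "_", nm, ".nii.gz")))
  }
  side <- c(list(method = fit$method), provenance)
  path <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flip-schedule CSV export/import
#'
#' CSV columns: `excitation`, `flip_deg`, `pe_line`.
#'
#' @param schedule A [flip_schedule()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "fam_schedule"))
  utils::write.csv(
    data.frame(excitation = seq_along(schedule$alphas_deg),
               flip_deg = schedule$alphas_deg,
               pe_line = schedule$pe_order),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param cap_deg Flip cap to record on the re-imported schedule.
#' @export
read_schedule_csv <- function(path, cap_deg = 90) {
  df <- utils::read.csv(path)
  df <- df[order(df$excitation), ]
  flip_schedule(df$flip_deg, df$pe_line, cap_deg = cap_deg)
}

#' Export a designed sequence as a Pulseq-style .seq text file
#'
#' Best-effort export of the FAM protocol as a version-tagged open sequence
#' text file: one block per excitation with a per-excitation-scaled RF pulse,
#' a trapezoidal phase-encode gradient for the scheduled PE line, and a
#' flyback multi-echo readout train. The file is timing-consistent at the
#' block level but is not vendor-certified.
#'
#' @param schedule A [flip_schedule()].
#' @param params A [acq_params()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pulseq_seq <- function(schedule, params, path) {
  stopifnot(inherits(schedule, "fam_schedule"), inherits(params, "fam_params"))
  ny <- params$matrix[2]
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# Pulseq sequence file (famfat export)")
  w("[VERSION]")
  w("major 1"); w("minor 4"); w("revision 0"); w("")
  w("[DEFINITIONS]")
  w("FOV ", params$fov_cm[1] / 100, " ", params$fov_cm[2] / 100, " ",
    params$slice_thickness_mm / 1000)
  w("TR ", params$tr_ms / 1000)
  w("TE ", paste(echo_times_ms(params) / 1000, collapse = " "))
  w("")
  # one RF shape reused with per-block amplitude scaling via the RF table
  w("[BLOCKS]")
  for (j in seq_len(ny)) {
    # block: duration rf gx gy gz adc ext
    w(sprintf("%4d %d %d %d %d %d %d %d", j,
              round(params$tr_ms * 1e5), j, 1, j, 0, 1, 0))
  }
  w("")
  w("[RF]")
  ref_deg <- max(schedule$alphas_deg)
  for (j in seq_len(ny)) {
    amp <- schedule$alphas_deg[j] / ref_deg
    w(sprintf("%4d %.6f 1 1 0 0 0", j, amp))
  }
  w("")
  w("[TRAP]")
  w("# id amplitude rise flat fall delay (readout 1, PE per line thereafter)")
  w(sprintf("%4d %.6f %d %d %d %d", 1L, 1.0, 100, round(params$dte_ms * 1e5), 100, 0))
  for (j in seq_len(ny)) {
    kline <- schedule$pe_order[j] - (ny %/% 2L + 1L)
    w(sprintf("%4d %.6f %d %d %d %d", j + 1L, kline / (ny / 2), 100, 800, 100, 0))
  }
  w("")
  w("[ADC]")
  w(sprintf("1 %d %d %d 0 0", params$matrix[1], 10L,
            round(params$te1_ms * 1e5)))
  invisible(path)
}
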