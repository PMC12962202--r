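#' Multi-echo complex image series
#'
#' Container for the simulator's output and the fitters' input: one complex
#' image per echo, the echo times, the acquisition parameters, and the noise
#' level / seed used.
#'
#' @param images List of complex matrices, one per echo, all of equal shape.
#' @param tes_ms Echo times (ms).
#' @param params The [acq_params()] used.
#' @param noise_sd Per-channel complex Gaussian noise SD (image units).
#' @param seed Integer seed used for the noise draw (or `NULL`).
#' @param mode `"fam"` or `"steady_state"`.
#' @return An object of class `fam_echoes`.
#' @export
echo_series <- function(images, tes_ms, params, noise_sd = 0, seed = NULL,
                        mode = "fam") {
  if (length(images) != length(tes_ms)) {
    stop("one image per echo time required", call. = FALSE)
  }
  dims <- dim(images[[1]])
  if (!all(vapply(images, function(im) identical(dim(im), dims), logical(1)))) {
    stop("all echo images must share the same shape", call. = FALSE)
  }
  structure(
    list(images = images, tes_ms = as.numeric(tes_ms), params = params,
         noise_sd = noise_sd, seed = seed, mode = mode),
    class = "fam_echoes"
  )
}

#' @export
print.fam_echoes <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("<fam_echoes> ", length(x$images), " echoes, ", d[1], "x", d[2],
      ", mode ", x$mode, ", noise_sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

# FFT along the phase-encode dimension (dim 2) of an image matrix
fft_pe <- function(img, inverse = FALSE) {
  out <- t(stats::mvfft(t(img), inverse = inverse))
  if (inverse) out / ncol(img) else out
}

# map per-PE-line weights (line order, DC at ny%/%2+1) to DFT bin order
weights_to_bins <- function(weights) {
  ny <- length(weights)
  dc <- ny %/% 2L + 1L
  freqs <- c(0:(ny - dc), -(dc - 1L):-1L)   # bin b carries frequency freqs[b]
  weights[dc + freqs]
}

# quantize a T1 map (over a mask) into at most max_classes discrete values
t1_classes <- function(t1_map, mask, max_classes = 32L) {
  vals <- t1_map[mask]
  u <- sort(unique(vals))
  if (length(u) <= max_classes) {
    return(list(values = u, index = match(t1_map, u)))
  }
  br <- stats::quantile(vals, probs = seq(0, 1, length.out = max_classes + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- findInterval(t1_map, br, rightmost.closed = TRUE)
  centers <- vapply(seq_len(max_classes),
                    function(b) mean(vals[bin[mask] == b]), numeric(1))
  list(values = centers, index = bin)
}

#' Forward-simulate a multi-echo acquisition of a digital phantom
#'
#' Evaluates the voxelwise CSE signal model at each echo and applies the
#' flip-schedule-induced k-space weighting separately per species and T1
#' class: for each echo, each species sub-image (water, fat with its phasor)
#' is Fourier transformed along the phase-encode dimension, each PE line is
#' scaled by the transient signal of that species' T1 under the schedule, and
#' the images are transformed back and summed. Constant-flip steady-state
#' mode applies the converged flat weighting instead (no filtering).
#' Complex Gaussian noise is added in the image domain (equivalent, under the
#' unitary Fourier transform, to white k-space noise).
#'
#' @param phantom A `fam_phantom` whose grids match `params$matrix`.
#' @param params A [acq_params()].
#' @param flip A [flip_schedule()] (FAM / transient mode) or a single numeric
#'   flip angle in degrees (constant-flip steady-state mode).
#' @param spectrum A [fat_spectrum()].
#' @param noise_sd Per-channel complex Gaussian noise SD; 0 for noiseless.
#' @param seed Integer seed for the noise draw (ignored when `noise_sd = 0`).
#' @param max_t1_classes Maximum number of discrete T1 classes per species
#'   used for the species-separable weighting (exact for piecewise-constant
#'   phantom T1 maps).
#' @return A [echo_series()].
#' @export
simulate_echoes <- function(phantom, params, flip, spectrum, noise_sd = 0,
                            seed = NULL, max_t1_classes = 32L) {
  stopifnot(inherits(phantom, "fam_phantom"), inherits(params, "fam_params"))
  if (!identical(as.integer(phantom$matrix), params$matrix)) {
    stop("phantom grid does not match the acquisition matrix", call. = FALSE)
  }
  fam_mode <- inherits(flip, "fam_schedule")
  tes <- echo_times_ms(params)
  te_s <- tes / 1000
  cn <- fat_phasor(spectrum, tes, params$b0_t)
  wmap <- phantom$m0 * (1 - phantom$pdff)
  fmap <- phantom$m0 * phantom$pdff
  mask <- phantom$m0 > 0
  decay_phase <- function(n) {
    exp((-phantom$r2star_s + 1i * 2 * pi * phantom$psi_hz) * te_s[n])
  }
  images <- vector("list", length(tes))
  if (!fam_mode) {
    alpha <- as.numeric(flip)
    gw <- spgr_steady_state(alpha, params$tr_ms, phantom$t1_water_ms)
    gf <- spgr_steady_state(alpha, params$tr_ms, phantom$t1_fat_ms)
    for (n in seq_along(tes)) {
      images[[n]] <- (wmap * gw + fmap * gf * cn[n]) * decay_phase(n)
    }
  } else {
    species <- list(
      list(amp = wmap, t1 = phantom$t1_water_ms, phasor = rep(1 + 0i, length(tes))),
      list(amp = fmap, t1 = phantom$t1_fat_ms, phasor = cn)
    )
    # per-species per-class k-space line weights
    plans <- lapply(species, function(sp) {
      cls <- t1_classes(sp$t1, mask, max_t1_classes)
      wbins <- lapply(cls$values, function(t1) {
        weights_to_bins(kspace_weighting(flip, params, t1)$weights)
      })
      list(cls = cls, wbins = wbins)
    })
    for (n in seq_along(tes)) {
      acc <- array(0i, dim(wmap))
      dp <- decay_phase(n)
      for (s in seq_along(species)) {
        sp <- species[[s]]; pl <- plans[[s]]
        base <- sp$amp * sp$phasor[n] * dp
        for (k in seq_along(pl$wbins)) {
          sel <- mask & (pl$cls$index == k)
          if (!any(sel)) next
          sub <- array(0i, dim(base)); sub[sel] <- base[sel]
          ksp <- fft_pe(sub)
          ksp <- sweep(ksp, 2, pl$wbins[[k]], "*")
          acc <- acc + fft_pe(ksp, inverse = TRUE)
        }
      }
      images[[n]] <- acc
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    d <- dim(images[[1]])
    for (n in seq_along(images)) {
      images[[n]] <- images[[n]] +
        complex(real = stats::rnorm(prod(d), sd = noise_sd),
                imaginary = stats::rnorm(prod(d), sd = noise_sd))
    }
  }
  echo_series(images, tes, params, noise_sd = noise_sd, seed = seed,
              mode = if (fam_mode) "fam" else "steady_state")
}

#' Repeated acquisitions differing only in noise
#'
#' Simulates `n_reps` acquisitions of the same phantom and protocol with
#' independent noise realizations (seeds `base_seed + 0:(n_reps-1)`), as used
#' for voxel-wise noise characterization.
#'
#' @inheritParams simulate_echoes
#' @param n_reps Number of repetitions, `>= 2`.
#' @param base_seed Seed of the first repetition.
#' @return List of [echo_series()] objects.
#' @export
repeat_acquisitions <- function(phantom, params, flip, spectrum, noise_sd,
                                n_reps, base_seed = 1L, max_t1_classes = 32L) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  lapply(seq_len(n_reps) - 1L, function(i) {
    simulate_echoes(phantom, params, flip, spectrum, noise_sd = noise_sd,
                    seed = as.integer(base_seed) + i,
                    max_t1_classes = max_t1_classes)
  })
}
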