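# independent brute-force oracles, coded directly from the model definitions
# (kept free of the package's internal helpers)

oracle_phasor <- function(offsets_ppm, amplitudes, temp_shift_ppm, te_ms, b0_t) {
  a <- amplitudes / sum(amplitudes)
  f_hz <- 42.5775 * b0_t * (offsets_ppm + temp_shift_ppm)
  acc <- 0 + 0i
  for (p in seq_along(a)) {
    acc <- acc + a[p] * exp(1i * 2 * pi * f_hz[p] * te_ms / 1000)
  }
  acc
}

oracle_cse <- function(m0, pdff, r2star_s, psi_hz, spectrum, tes_ms, b0_t) {
  w <- m0 * (1 - pdff); f <- m0 * pdff
  out <- complex(length(tes_ms))
  for (n in seq_along(tes_ms)) {
    cn <- oracle_phasor(spectrum$offsets_ppm, spectrum$amplitudes,
                        spectrum$temp_shift_ppm, tes_ms[n], b0_t)
    te <- tes_ms[n] / 1000
    out[n] <- (w + f * cn) * exp(-r2star_s * te) * exp(1i * 2 * pi * psi_hz * te)
  }
  out
}

# dense direct-summation PSF; x in voxel units
oracle_psf <- function(w, oversample = 128L) {
  ny <- length(w)
  dc <- ny %/% 2 + 1
  x <- seq(-ny / 2, ny / 2, by = 1 / oversample)
  y <- vapply(x, function(xx) {
    Mod(sum(w * exp(1i * 2 * pi * (seq_len(ny) - dc) * xx / ny)))
  }, numeric(1))
  list(x = x, y = y)
}

oracle_fwhm <- function(w, oversample = 128L) {
  p <- oracle_psf(w, oversample)
  pk <- which.max(p$y)
  half <- p$y[pk] / 2
  above <- p$y > half
  # contiguous run around the peak
  lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  p$x[hi] - p$x[lo]
}

# explicit-DFT forward model of the species-weighted FAM acquisition
oracle_fam_image <- function(phantom, params, schedule, spectrum, echo_n) {
  tes <- echo_times_ms(params)
  te_s <- tes[echo_n] / 1000
  cn <- oracle_phasor(spectrum$offsets_ppm, spectrum$amplitudes,
                      spectrum$temp_shift_ppm, tes[echo_n], params$b0_t)
  ny <- params$matrix[2]
  dc <- ny %/% 2 + 1
  # DFT matrices along the PE dimension, line l <-> frequency (l - dc)
  x <- seq_len(ny)
  Fmat <- exp(-1i * 2 * pi * outer(x - dc, x - 1) / ny)       # line x voxel
  Finv <- exp(1i * 2 * pi * outer(x - 1, x - dc) / ny) / ny   # voxel x line
  dp <- exp((-phantom$r2star_s + 1i * 2 * pi * phantom$psi_hz) * te_s)
  mask <- phantom$m0 > 0
  acc <- array(0i, dim(phantom$m0))
  species <- list(
    list(amp = phantom$m0 * (1 - phantom$pdff), t1 = phantom$t1_water_ms,
         ph = 1 + 0i),
    list(amp = phantom$m0 * phantom$pdff, t1 = phantom$t1_fat_ms, ph = cn)
  )
  for (sp in species) {
    for (t1 in unique(sp$t1[mask])) {
      sub <- sp$amp * sp$ph * dp
      sub[!(mask & sp$t1 == t1)] <- 0
      s <- transient_signal(schedule, params$tr_ms, t1)
      wline <- numeric(ny); wline[schedule$pe_order] <- s
      ksp <- sub %*% t(Fmat)                 # voxel-rows x PE-lines
      ksp <- sweep(ksp, 2, wline, "*")
      acc <- acc + ksp %*% t(Finv)
    }
  }
  acc
}
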