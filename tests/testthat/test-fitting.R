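test_that("magnitude fit recovers noiseless vial parameters", {
  p <- small_params()
  ph <- small_phantom(p)
  sp <- phantom_spectrum()
  sched <- solve_fam_schedule(p)
  ser <- simulate_echoes(ph, p, sched, sp)
  fit <- magnitude_fit(ser, sp, mask = ph$m0 > 0.5)
  tab <- roi_summary(fit, vial_rois(ph, 1.4))
  expect_true(all(abs(tab$mean - 100 * tab$pdff) <= 0.1))
  r2tab <- roi_summary(fit, vial_rois(ph, 1.4), value = "r2star")
  expect_true(all(abs(r2tab$mean - 40) <= 0.5))
  # background voxels are flagged invalid, not errors
  expect_false(any(fit$valid[ph$m0 == 0]))
  expect_true(all(is.na(fit$pdff[ph$m0 == 0])))
})

test_that("magnitude fit handles water-only and balanced voxels", {
  p <- protocol_preset("3T")
  sp <- phantom_spectrum()
  serw <- voxel_series(tissue_voxel(pdff = 0, r2star_s = 30), sp, p)
  fw <- magnitude_fit(serw, sp)
  expect_equal(fw$pdff[1, 1], 0, tolerance = 1e-4)
  expect_lt(fw$residual[1, 1], 1e-16)
  # PDFF exactly 50%: the dominance-ambiguous point; both initializations
  # meet at the symmetric solution
  ser5 <- voxel_series(tissue_voxel(pdff = 0.5, r2star_s = 30), sp, p)
  f5 <- magnitude_fit(ser5, sp)
  expect_equal(f5$pdff[1, 1], 50, tolerance = 0.1)
  expect_lt(f5$residual[1, 1], 1e-16)
})

test_that("magnitude fitting is invariant to voxelwise phase", {
  ph <- tiny_phantom(pdff = 0.2, t1w = 700)
  p <- protocol_preset("3T"); p$matrix <- c(24L, 24L); p$fov_cm <- c(7.2, 7.2)
  sp <- phantom_spectrum()
  ser <- simulate_echoes(ph, p, 3, sp)
  set.seed(8)
  phase <- matrix(runif(24 * 24, -pi, pi), 24, 24)
  ser2 <- ser
  ser2$images <- lapply(ser$images, function(im) im * exp(1i * phase))
  f1 <- magnitude_fit(ser, sp, mask = ph$m0 > 0.5)
  f2 <- magnitude_fit(ser2, sp, mask = ph$m0 > 0.5)
  expect_equal(f1$pdff, f2$pdff, tolerance = 1e-8)
  expect_equal(f1$r2star_s, f2$r2star_s, tolerance = 1e-8)
})

test_that("field-map estimation recovers uniform offsets within the grid step", {
  p <- protocol_preset("3T"); p$matrix <- c(24L, 24L); p$fov_cm <- c(7.2, 7.2)
  sp <- phantom_spectrum()
  step <- (1000 / p$dte_ms) / 80
  for (psi_true in c(0, 25)) {
    ph <- tiny_phantom(pdff = 0.2, t1w = 700, psi_hz = psi_true)
    ser <- simulate_echoes(ph, p, 3, sp)
    psi <- estimate_field_map(ser, sp)
    expect_true(all(abs(psi[ph$m0 > 0.5] - psi_true) <= step + 1e-9))
  }
  expect_error(estimate_field_map(simulate_echoes(tiny_phantom(), p, 3, sp),
                                  sp, n_psi = 11), "too coarse")
})

test_that("unregularized data term has its minimum at the true field offset", {
  p <- protocol_preset("3T")
  sp <- phantom_spectrum()
  vx <- tissue_voxel(pdff = 0.3, r2star_s = 40, psi_hz = 30)
  ser <- voxel_series(vx, sp, p)
  psi <- estimate_field_map(ser, sp, lambda_smooth = 0)
  grid <- attr(psi, "psi_grid")
  step <- grid[2] - grid[1]
  expect_lte(abs(psi[1, 1] - 30), step)
  # independent exhaustive scan of the projection residual
  tes_s <- echo_times_ms(p) / 1000
  cn <- fat_phasor(sp, echo_times_ms(p), 3.0)
  s <- cse_signal(vx, sp, echo_times_ms(p), 3.0)
  D <- vapply(grid, function(psi_g) {
    d <- s * exp(-1i * 2 * pi * psi_g * tes_s)
    min(vapply(seq(0, 200, 25), function(r2) {
      A <- cbind(exp(-r2 * tes_s) + 0i, cn * exp(-r2 * tes_s))
      B <- solve(Conj(t(A)) %*% A, Conj(t(A)) %*% d)
      sum(Mod(d - A %*% B)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(psi[1, 1], grid[which.min(D)])
})

test_that("field-map smoothing drives the map toward a constant as lambda grows", {
  p <- protocol_preset("3T"); p$matrix <- c(24L, 24L); p$fov_cm <- c(7.2, 7.2)
  sp <- phantom_spectrum()
  # linear field ramp across the vial
  ph <- tiny_phantom(pdff = 0.2, t1w = 700,
                     psi_hz = function(x, y) 8 * x)
  ser <- simulate_echoes(ph, p, 3, sp, noise_sd = 0.005, seed = 2)
  tv <- function(m) sum(abs(m[-1, ] - m[-nrow(m), ])) +
    sum(abs(m[, -1] - m[, -ncol(m)]))
  tvs <- vapply(c(0, 0.02, 0.5, 50), function(l) {
    tv(estimate_field_map(ser, sp, lambda_smooth = l))
  }, numeric(1))
  expect_true(all(diff(tvs) <= 1e-9))
  expect_equal(tvs[4], 0)
  # ICM energy is non-increasing sweep to sweep
  psi <- estimate_field_map(ser, sp, lambda_smooth = 0.02)
  expect_true(all(diff(attr(psi, "energy_trace")) <= 1e-9))
})

test_that("complex fit is exact given the true field map and swaps under aliasing", {
  p <- protocol_preset("3T")
  sp <- phantom_spectrum()
  vx <- tissue_voxel(m0 = 2, pdff = 0.3, r2star_s = 40, psi_hz = 17)
  s <- cse_signal(vx, sp, echo_times_ms(p), 3.0)
  ser <- echo_series(lapply(s, function(v) matrix(v, 1, 1)),
                     echo_times_ms(p), p)
  fit <- complex_fit(ser, matrix(17, 1, 1), sp)
  expect_equal(fit$pdff[1, 1], 30, tolerance = 1e-6)
  expect_equal(fit$water[1, 1], 2 * 0.7, tolerance = 1e-6)
  expect_equal(fit$fat[1, 1], 2 * 0.3, tolerance = 1e-6)
  expect_equal(fit$r2star_s[1, 1], 40, tolerance = 1e-3)
  # single-peak fat at out-phase echo spacing: a field-map error equal to the
  # fat-water frequency swaps the species
  sp1 <- fat_spectrum(-3.4, 1)
  f1 <- 42.5775 * 3.0 * (-3.4)           # Hz, negative
  dte <- -0.5 / f1 * 1000                # ms, so f1 * dTE = -1/2 cycle
  pa <- acq_params(b0_t = 3, tr_ms = 20, te1_ms = dte, dte_ms = dte,
                   n_echoes = 6)
  vx2 <- tissue_voxel(pdff = 0.2, r2star_s = 0, psi_hz = 0)
  s2 <- cse_signal(vx2, sp1, echo_times_ms(pa), 3.0)
  ser2 <- echo_series(lapply(s2, function(v) matrix(v, 1, 1)),
                      echo_times_ms(pa), pa)
  swapped <- complex_fit(ser2, matrix(-f1, 1, 1), sp1)
  expect_equal(swapped$pdff[1, 1], 80, tolerance = 1e-4)
  # zero-signal voxel flagged invalid
  ser0 <- echo_series(lapply(1:6, function(i) matrix(0i, 1, 1)),
                      echo_times_ms(p), p)
  f0 <- complex_fit(ser0, matrix(0, 1, 1), sp)
  expect_false(f0$valid[1, 1])
})

test_that("hybrid fit interpolates between magnitude and complex fitting", {
  p <- protocol_preset("3T"); p$matrix <- c(24L, 24L); p$fov_cm <- c(7.2, 7.2)
  sp <- phantom_spectrum()
  ph <- tiny_phantom(pdff = 0.2, t1w = 700, psi_hz = 12)
  ser <- simulate_echoes(ph, p, 3, sp)
  mask <- ph$m0 > 0.5
  psi_true <- array(12, dim(ph$m0))
  fm <- magnitude_fit(ser, sp, mask = mask)
  fc <- complex_fit(ser, psi_true, sp, mask = mask)
  h0 <- hybrid_fit(ser, sp, weight_w = 0, psi_map = psi_true, mask = mask)
  h1 <- hybrid_fit(ser, sp, weight_w = 1, psi_map = psi_true, mask = mask)
  expect_equal(h0$pdff, fm$pdff, tolerance = 1e-9)
  expect_equal(h1$pdff, fc$pdff, tolerance = 1e-9)
  h5 <- hybrid_fit(ser, sp, weight_w = 0.5, psi_map = psi_true, mask = mask)
  pred <- 100 * apparent_pdff_steady_state(0.2, 3, p$tr_ms, 700, 300)
  expect_true(all(abs(h5$pdff[mask] - pred) <= 0.1))
  expect_error(hybrid_fit(ser, sp, weight_w = 2), "0, 1")
})

test_that("steady-state T1 correction restores the true PDFF under a matched model", {
  p <- small_params()
  ph <- small_phantom(p)
  sp <- phantom_spectrum()
  ser <- simulate_echoes(ph, p, 3, sp)
  fit <- magnitude_fit(ser, sp, mask = ph$m0 > 0.5)
  fitc <- correct_steady_state_t1(fit, 3, p$tr_ms, ph$t1_water_ms, ph$t1_fat_ms)
  tab <- roi_summary(fitc, vial_rois(ph, 1.4))
  expect_true(all(abs(tab$mean - 100 * tab$pdff) <= 0.1))
})
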