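test_that("centric ordering starts at DC and alternates outward", {
  expect_identical(centric_order(1), 1L)
  # forced by the alternation rule, positive offset first (1-based lines)
  expect_identical(centric_order(6), c(4L, 5L, 3L, 6L, 2L, 1L))
  ord <- centric_order(144)
  expect_identical(sort(ord), 1:144)
  expect_identical(ord[1], 73L)
  expect_true(all(diff(abs(ord - 73L)) >= 0))
  ord5 <- centric_order(5)
  expect_identical(sort(ord5), 1:5)
  expect_identical(ord5[1], 3L)
  expect_error(centric_order(0), ">= 1")
})

test_that("transient recursion honours the equilibrium start and known cases", {
  # first-excitation signal is T1-independent for random schedules
  set.seed(5)
  for (i in 1:10) {
    alphas <- runif(20, 1, 60)
    s1 <- vapply(c(100, 300, 800, 1400, 3000), function(t1) {
      transient_signal(alphas, tr_ms = 10, t1_ms = t1, m0 = 2)[1]
    }, numeric(1))
    expect_equal(max(s1) - min(s1), 0, tolerance = 1e-14)
    expect_equal(s1[1], 2 * sin(alphas[1] * pi / 180), tolerance = 1e-14)
  }
  # two 90-degree pulses: Mz fully consumed then recovers (1 - E1)
  s <- transient_signal(c(90, 90), tr_ms = 100, t1_ms = 100, m0 = 3)
  expect_equal(s[2], 3 * (1 - exp(-1)), tolerance = 1e-12)
  # constant flip converges to the closed-form steady state
  s <- transient_signal(3, 6.4, 809, n_pulses = 5000)
  expect_equal(s[5000], spgr_steady_state(3, 6.4, 809), tolerance = 1e-10)
  expect_true(all(diff(abs(s - spgr_steady_state(3, 6.4, 809))) <= 1e-15))
})

test_that("k-space weighting maps transient signals onto PE lines", {
  p <- small_params()
  ny <- p$matrix[2]
  sched <- flip_schedule(rep(5, ny))
  # steady-state mode: flat weighting
  wss <- kspace_weighting(sched, p, 800, mode = "steady_state")
  expect_equal(wss$weights, rep(spgr_steady_state(5, p$tr_ms, 800), ny))
  # transient mode agrees with the recursion reordered by pe_order
  ramp <- flip_schedule(seq(4, 12, length.out = ny))
  for (t1 in c(300, 1400)) {
    kw <- kspace_weighting(ramp, p, t1)
    s <- transient_signal(ramp, p$tr_ms, t1)
    expect_equal(kw$weights[ramp$pe_order], s, tolerance = 1e-14)
  }
  # DC weight equals sin(alpha_1) regardless of T1
  dcw <- vapply(c(200, 600, 1000, 1400), function(t1) {
    kw <- kspace_weighting(ramp, p, t1)
    kw$weights[ramp$pe_order[1]]
  }, numeric(1))
  expect_equal(max(dcw) - min(dcw), 0, tolerance = 1e-14)
  expect_equal(dcw[1], sin(4 * pi / 180), tolerance = 1e-14)
})

test_that("PSF metrics recover the box baseline and match a dense DFT oracle", {
  m <- psf_metrics(rep(1, 64))
  expect_equal(m$fwhm_broadening, 1, tolerance = 1e-6)
  # box window sidelobe of |sin(N x)/sin(x)| is about 0.217
  expect_equal(m$max_sidelobe, 0.217, tolerance = 0.01)
  # Hann-shaped weights against the direct-summation oracle
  n <- 64
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  hann <- hann + 1e-6  # strictly positive weights
  m <- psf_metrics(hann)
  expect_equal(m$fwhm_broadening, oracle_fwhm(hann) / oracle_fwhm(rep(1, n)),
               tolerance = 0.01)
  delta <- c(rep(0, 32), 1, rep(0, 31))
  expect_error(psf_metrics(delta), "degenerate")
})

test_that("FAM schedule solving tracks its target and respects the cap", {
  p <- protocol_preset("1.5T")
  ny <- p$matrix[2]
  # constant target at the steady-state level of alpha*: schedule converges
  alpha_star <- 5
  ss <- spgr_steady_state(alpha_star, p$tr_ms, 300)
  sched <- solve_fam_schedule(p, t1_refs = c(300, 300),
                              target = rep(ss, ny))
  expect_equal(tail(sched$alphas_deg, 1), alpha_star, tolerance = 1e-3)
  # flat target at sin(alpha_1): increasing flips while Mz decays
  sched2 <- solve_fam_schedule(p, t1_refs = c(300, 1000),
                               target = rep(sin(6 * pi / 180), ny))
  expect_true(all(diff(sched2$alphas_deg[1:10]) > 0))
  # round trip: simulated signal reproduces the target on uncapped excitations
  sched3 <- solve_fam_schedule(p)
  d <- attr(sched3, "design")
  sim <- transient_signal(sched3, p$tr_ms, d$t1_refs[2])
  expect_equal(sim[!d$capped], d$target[!d$capped], tolerance = 1e-8)
  expect_false(any(d$capped))   # default design never hits the cap
  # infeasible target
  expect_error(
    solve_fam_schedule(p, target = rep(0.9, ny), cap_deg = 10),
    "infeasible"
  )
})

test_that("PDFF CRLB scales quadratically with noise and flags singularity", {
  p <- protocol_preset("3T")
  sp <- default_fat_spectrum(phantom = TRUE)
  vx <- tissue_voxel(pdff = 0.2, r2star_s = 50)
  v1 <- crlb_pdff_variance(p, vx, sp, noise_sd = 0.02)
  v2 <- crlb_pdff_variance(p, vx, sp, noise_sd = 0.04)
  expect_equal(v2 / v1, 4, tolerance = 1e-9)
  # echoes all in-phase with a single fat peak: no fat-water contrast
  f1 <- abs(42.5775 * 3.0 * (-3.4))
  per_ms <- 1000 / f1
  pip <- acq_params(b0_t = 3, tr_ms = 20, te1_ms = per_ms, dte_ms = per_ms,
                    n_echoes = 6)
  sp1 <- fat_spectrum(-3.4, 1)
  expect_warning(v <- crlb_pdff_variance(pip, vx, sp1, 0.02), "singular")
  expect_identical(v, Inf)
})

test_that("per-slice temporal footprints reproduce the protocol table", {
  cases <- list(
    list(preset = "0.55T", per_slice = 1.7, total = 54.4),
    list(preset = "1.5T", per_slice = 1.8, total = 57.6),
    list(preset = "3T", per_slice = 1.3, total = 41.6)
  )
  for (cs in cases) {
    tm <- sequence_timing(protocol_preset(cs$preset))
    expect_equal(tm$per_slice_rounded_s, cs$per_slice)
    expect_equal(tm$total_s, cs$total)
  }
})

test_that("preset loading and schedule CSV round trip preserve the design", {
  p <- protocol_preset("3T")
  expect_equal(echo_times_ms(p), 1.21 + 0:5 * 1.22, tolerance = 1e-12)
  expect_error(protocol_preset("7T"), "unknown preset")
  sched <- solve_fam_schedule(small_params())
  path <- tempfile(fileext = ".csv")
  write_schedule_csv(sched, path)
  back <- read_schedule_csv(path)
  expect_equal(back$alphas_deg, sched$alphas_deg, tolerance = 1e-10)
  expect_identical(back$pe_order, sched$pe_order)
})
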