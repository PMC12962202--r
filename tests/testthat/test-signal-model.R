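test_that("fat phasor is unity at TE 0 and after a full phase cycle", {
  set.seed(11)
  for (i in 1:5) {
    np <- sample(2:7, 1)
    sp <- fat_spectrum(runif(np, -4, 1), runif(np), temp_shift_ppm = runif(1, 0, 0.2))
    expect_equal(fat_phasor(sp, 0, b0_t = runif(1, 0.5, 7)), 1 + 0i, tolerance = 1e-12)
  }
  # single peak at -3.4 ppm, TE chosen so f * TE is exactly -1 cycle
  sp1 <- fat_spectrum(-3.4, 1)
  f1 <- 42.5775 * 3.0 * (-3.4)
  te_cycle <- -1000 / f1
  z <- fat_phasor(sp1, te_cycle, 3.0)
  expect_equal(Re(z), 1, tolerance = 1e-12)
  expect_equal(Im(z), 0, tolerance = 1e-12)
})

test_that("six-peak phasor matches the brute-force summation oracle", {
  sp <- default_fat_spectrum()
  z <- fat_phasor(sp, 1.21, 3.0)
  # value frozen from an independent term-by-term summation
  expect_equal(Re(z), -0.7884872426939156, tolerance = 1e-12)
  expect_equal(Im(z), 0.09013966064742199, tolerance = 1e-12)
  # and across TEs / field strengths, including the phantom temperature shift
  spph <- default_fat_spectrum(phantom = TRUE)
  for (te in c(0.8, 1.21, 2.5)) {
    for (b0 in c(1.5, 3.0)) {
      expect_equal(fat_phasor(spph, te, b0),
                   oracle_phasor(spph$offsets_ppm, spph$amplitudes, 0.11, te, b0),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(Mod(fat_phasor(sp, seq(0, 10, by = 0.1), 3)) <= 1 + 1e-12))
})

test_that("spectrum constructor normalizes amplitudes and rejects bad input", {
  sp <- default_fat_spectrum()
  expect_equal(sum(sp$amplitudes), 1, tolerance = 1e-12)
  expect_error(fat_spectrum(numeric(0), numeric(0)), "length")
  expect_error(fat_spectrum(c(-3.4, 0.6), 1), "length")
  expect_error(fat_phasor(default_fat_spectrum(), -1, 3), "nonnegative")
})

test_that("cse_signal reduces to known limits and matches an independent oracle", {
  sp <- default_fat_spectrum(phantom = TRUE)
  tes <- echo_times_ms(protocol_preset("3T"))
  # water-only voxel: real, monoexponential (log-linear to 1e-12)
  vx <- tissue_voxel(m0 = 2, pdff = 0, r2star_s = 60, psi_hz = 0)
  s <- cse_signal(vx, sp, tes, 3.0)
  expect_equal(Im(s), rep(0, 6), tolerance = 1e-12)
  lm_res <- stats::lm(log(Re(s)) ~ I(tes / 1000))
  expect_lt(max(abs(stats::residuals(lm_res))), 1e-12)
  expect_equal(unname(stats::coef(lm_res)[2]), -60, tolerance = 1e-9)
  # pure fat, single peak, no decay: a bare phasor
  sp1 <- fat_spectrum(-3.4, 1)
  vf <- tissue_voxel(m0 = 1.5, pdff = 1)
  f1 <- 42.5775 * 3.0 * (-3.4)
  expect_equal(cse_signal(vf, sp1, tes, 3.0),
               1.5 * exp(1i * 2 * pi * f1 * tes / 1000), tolerance = 1e-12)
  # full model against the independently coded evaluation
  vm <- tissue_voxel(pdff = 0.3, r2star_s = 50, psi_hz = 30)
  got <- cse_signal(vm, default_fat_spectrum(), tes, 3.0)
  expect_equal(got, oracle_cse(1, 0.3, 50, 30, default_fat_spectrum(), tes, 3.0),
               tolerance = 1e-12)
  # and against values frozen from a separate implementation
  frozen <- complex(
    real = c(0.419193051795, 0.762059224729, 0.293187160053,
             0.465019975110, 0.080250959406, 0.236272049772),
    imaginary = c(0.123433614145, 0.323789587801, 0.347591106106,
                  0.435139510991, 0.462308432137, 0.459153292068)
  )
  expect_equal(got, frozen, tolerance = 1e-9)
  expect_error(cse_signal(vm, sp, c(2, 1, 3), 3.0), "increasing")
})

test_that("SPGR steady state obeys its limits and the transient recursion", {
  # full recovery limit and 90-degree limit
  expect_equal(spgr_steady_state(30, 1e6, 100), sin(30 * pi / 180), tolerance = 1e-9)
  e1 <- exp(-10 / 500)
  expect_equal(spgr_steady_state(90, 10, 500), 1 - e1, tolerance = 1e-12)
  # monotone decreasing in T1 at small flip
  vals <- spgr_steady_state(3, 6.4, c(200, 600, 1000, 1400))
  expect_true(all(diff(vals) < 0))
  # agreement with the converged recursion for random (alpha, TR, T1)
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 1, 90); tr <- runif(1, 3, 20); t1 <- runif(1, 100, 2000)
    n <- max(5000L, ceiling(35 * t1 / tr))
    s <- transient_signal(a, tr, t1, n_pulses = n)
    expect_equal(s[n], spgr_steady_state(a, tr, t1), tolerance = 1e-10)
  }
})

test_that("steady-state apparent PDFF reproduces the closed-form bias example", {
  # a 3 deg / TR 6.4 ms acquisition reads true 30% as 31.7% (one decimal)
  app <- apparent_pdff_steady_state(0.30, 3, 6.4,
                                    t1_water_ms = 809, t1_fat_ms = 382)
  expect_equal(round(100 * app, 1), 31.7)
  # equal T1s: no bias, exactly
  expect_identical(apparent_pdff_steady_state(0.3, 10, 8, 500, 500), 0.3)
  # alpha -> 0 limit removes the bias
  expect_equal(apparent_pdff_steady_state(0.3, 1e-4, 6.4, 809, 382), 0.3,
               tolerance = 1e-8)
  # overestimation whenever fat T1 < water T1 and PDFF is interior
  set.seed(21)
  for (i in 1:20) {
    pd <- runif(1, 0.05, 0.95)
    t1w <- runif(1, 500, 2000); t1f <- runif(1, 100, t1w - 50)
    expect_gte(apparent_pdff_steady_state(pd, runif(1, 1, 20), 8, t1w, t1f), pd)
  }
})
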