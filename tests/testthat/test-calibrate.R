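# Calibration routines exercised against the virtual scanner at a 50 kS/s
# desk configuration (12.3 kHz carrier, 2.5 kHz receive bandwidth).

calib_params <- function(...) {
  acq_params(larmor_frequency = 12300, receive_bandwidth = 2500,
             raw_sample_rate = 5e4, output_full_scale = 4000, ...)
}

test_that("the Larmor search recovers off-resonance from the FID spectrum", {
  p <- calib_params()
  be <- virtual_backend(make_phantom("point", t2 = 0.2, off_resonance = 500),
                        p, signal_scale = 200, seed = 5)
  r <- find_larmor(be)
  expect_true(r$converged)
  expect_lt(abs(r$value - (p$larmor_frequency + 500)), 5)

  be0 <- virtual_backend(make_phantom("point", t2 = 0.2), p,
                         signal_scale = 200, seed = 5)
  r0 <- find_larmor(be0)
  expect_lt(abs(r0$value - p$larmor_frequency), 5)

  # pure noise: flagged non-converged
  ben <- virtual_backend(make_phantom("point", t2 = 1), p, signal_scale = 0,
                         noise_sd = 2, seed = 9)
  expect_false(find_larmor(ben)$converged)
})

test_that("RF amplitude calibration finds the 90-degree point", {
  p <- calib_params()
  ph <- make_phantom("point", t2 = 0.2)
  be <- virtual_backend(ph, p, signal_scale = 200, seed = 5)
  grid <- seq(450, 2050, by = 200)           # includes the true 1250 Hz point
  r <- calibrate_rf_amplitude(be, grid)
  expect_true(r$converged)
  expect_lt(abs(r$value - 1250), 200)        # within one grid step of 0.25/dur

  # doubling the B1 scaling halves the amplitude needed for 90 degrees
  p2 <- calib_params(b1_scaling = 2)
  be2 <- virtual_backend(ph, p2, signal_scale = 200, seed = 5)
  r2 <- calibrate_rf_amplitude(be2, seq(200, 1200, by = 100))
  expect_lt(abs(r2$value - 625), 100)

  # a grid that misses the optimum is flagged
  r_edge <- calibrate_rf_amplitude(be, seq(200, 800, by = 200))
  expect_false(r_edge$converged)

  # the FID integral objective is symmetric about the 90-degree amplitude
  obj <- r$objective
  i0 <- which.min(abs(grid - 1250))
  expect_equal(obj[i0 - 2], obj[i0 + 2], tolerance = 0.05)
})

test_that("shim calibration cancels an injected linear inhomogeneity", {
  p <- calib_params()
  ph <- make_phantom("sphere", n_spins = 200, extent = 0.06, t2 = 0.3)
  ph$off_resonance <- 4000 * ph$pos[, 1]     # 4 kHz/m along x
  be <- virtual_backend(ph, p, signal_scale = 5, seed = 5)
  grid <- seq(-400, 400, by = 100)
  r <- calibrate_shim(be, grid)
  expect_true(r$converged)
  # offset o adds field o / scaling kHz/m; -200 mV cancels 4 kHz/m at 50
  expect_lt(abs(r$value[1] - (-200)), 100)
  expect_lt(abs(r$value[2]), 100)
  expect_lt(abs(r$value[3]), 100)

  # homogeneous phantom: offsets stay near zero
  ph0 <- make_phantom("sphere", n_spins = 200, extent = 0.06, t2 = 0.3)
  r0 <- calibrate_shim(virtual_backend(ph0, p, signal_scale = 5, seed = 5), grid)
  expect_true(all(abs(r0$value) < 100))

  # the objective worsens as the offsets leave the optimum (main lobe)
  obj_x <- r$objective[[1]]
  i <- which.max(obj_x)
  expect_true(all(diff(obj_x[max(1, i - 2):i]) > 0))
  expect_true(all(diff(obj_x[i:min(length(obj_x), i + 2)]) < 0))
  expect_gt(obj_x[i], 2 * max(obj_x[1], obj_x[length(obj_x)]))
})

test_that("gradient delay estimation reaches sub-sample precision", {
  fs <- 1e5
  t <- (0:2999) / fs
  w <- exp(-((t - 0.01) / 5e-4)^2)     # band-limited monitoring transient
  shift_frac <- function(x, s) {
    n <- length(x)
    k <- c(0:(n / 2 - 1), -(n / 2):-1)
    Re(stats::fft(stats::fft(x) * exp(-2i * pi * k * s / n), inverse = TRUE) / n)
  }
  expect_equal(estimate_gradient_delay(w, shift_frac(w, 16), fs) * fs, 16,
               tolerance = 1e-6)                       # 160 us at 100 kS/s
  expect_equal(estimate_gradient_delay(w, w, fs), 0)
  expect_lt(abs(estimate_gradient_delay(w, shift_frac(w, 3.2), fs) * fs - 3.2),
            0.1)
  set.seed(30)
  expect_error(estimate_gradient_delay(w, rnorm(3000), fs, min_correlation = 0.2),
               "threshold")
})

test_that("calibrations are pure functions of backend output and grids", {
  p <- calib_params()
  be <- virtual_backend(make_phantom("point", t2 = 0.2, off_resonance = 321),
                        p, noise_sd = 0.5, signal_scale = 200, seed = 17)
  r1 <- find_larmor(be)
  r2 <- find_larmor(be)
  expect_identical(r1, r2)
})
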