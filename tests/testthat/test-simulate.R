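test_that("an on-resonance point phantom gives a flat FID baseband", {
  p <- desk_params(output_full_scale = 2000)
  u <- unroll_sequence(make_fid(rf_duration = 2e-4, adc_duration = 6.4e-3,
                                readout_bandwidth = 5e3), p)
  ph <- make_phantom("point", t2 = 1e6)
  raw <- simulate_acquisition(u, ph, p, signal_scale = 100, seed = 3)
  bb <- receive_chain(raw, p)$data[1, 1, 1, ]
  centre <- 6:27                       # outside the FIR warm-up transients
  expect_lt(max(abs(Mod(bb[centre]) - 100)), 1)   # constant magnitude
})

test_that("frequency encoding follows the analytic g * x relation", {
  p <- desk_params()
  blocks <- list(
    seq_block(2e-4, rf = rf_event(0.25 / 2e-4, 2e-4)),
    seq_block(8e-3, gx = trap_event(80, 2e-4, 7.2e-3, 2e-4),
              adc = adc_event(32, 2e-4, delay = 8e-4)))
  u <- unroll_sequence(seq_def(blocks = blocks), p)
  ph <- make_phantom("point", t2 = 1)
  ph$pos[1, 1] <- 0.01
  raw <- simulate_acquisition(u, ph, p, signal_scale = 1000, seed = 1)
  bb <- receive_chain(raw, p)$data[1, 1, 1, ]
  dwell <- 1 / p$receive_bandwidth
  f_est <- mean(Arg(bb[9:25] / bb[8:24])) / (2 * pi * dwell)
  expect_equal(f_est, 80 * 0.01 * 1000, tolerance = 0.01)  # 0.8 kHz
})

test_that("identical seeds give bit-identical raw acquisitions", {
  p <- desk_params(num_rx_channels = 2L)
  u <- unroll_sequence(make_fid(readout_bandwidth = 5e3, adc_duration = 2e-3), p)
  ph <- make_phantom("sphere", n_spins = 60, extent = 0.05, t2 = 0.1)
  emi <- make_emi("tone", 100, frequency = 22e3, n_channels = 2L, seed = 4L)
  r1 <- simulate_acquisition(u, ph, p, emi = list(emi), noise_sd = 1, seed = 9)
  r2 <- simulate_acquisition(u, ph, p, emi = list(emi), noise_sd = 1, seed = 9)
  expect_identical(r1$blocks, r2$blocks)
  r3 <- simulate_acquisition(u, ph, p, emi = list(emi), noise_sd = 1, seed = 10)
  expect_false(identical(r3$blocks, r2$blocks))
})

test_that("EMI sources superpose linearly before quantization", {
  p <- desk_params(num_rx_channels = 3L)
  u <- unroll_sequence(make_fid(readout_bandwidth = 5e3, adc_duration = 2e-3), p)
  ph <- make_phantom("point", t2 = 0.05)
  e1 <- make_emi("tone", 150, frequency = 20e3, n_channels = 3L, seed = 21L)
  e2 <- make_emi("broadband", 80, band = c(18e3, 26e3), n_channels = 3L,
                 seed = 22L)
  run <- function(srcs) simulate_acquisition(u, ph, p, emi = srcs, seed = 5,
                                             signal_scale = 50,
                                             return_analog = TRUE)$analog[[1]]
  a0 <- run(list()); a1 <- run(list(e1)); a2 <- run(list(e2))
  a12 <- run(list(e1, e2))
  expect_equal(a12, a1 + a2 - a0, tolerance = 1e-10)
})

test_that("tone and broadband EMI land where expected in the sensor spectrum", {
  p <- desk_params(num_rx_channels = 2L)
  u <- unroll_sequence(make_fid(readout_bandwidth = 5e3,
                                adc_duration = 25.6e-3), p)
  ph <- make_phantom("point", t2 = 0.05)
  sensor_spec <- function(src) {
    raw <- simulate_acquisition(u, ph, p, emi = if (is.null(src)) list() else list(src),
                                seed = 2, signal_scale = 50)
    bb <- receive_chain(raw, p)$data[1, 2, 1, ]
    Mod(stats::fft(bb))
  }
  # tone at f0 + 1.5 kHz: a single line in the demodulated sensor channel
  tone <- make_emi("tone", 200, frequency = p$larmor_frequency + 1500,
                   n_channels = 2L, seed = 31L)
  spec <- sensor_spec(tone)
  n <- length(spec)
  freqs <- (seq_len(n) - 1) / (n / p$receive_bandwidth)
  freqs[freqs >= p$receive_bandwidth / 2] <-
    freqs[freqs >= p$receive_bandwidth / 2] - p$receive_bandwidth
  expect_lt(abs(freqs[which.max(spec)] - 1500), p$receive_bandwidth / n)
  expect_gt(max(spec), 20 * median(spec))     # a line, not a plateau

  # zero-amplitude source changes nothing
  silent <- make_emi("tone", 0, frequency = 22e3, n_channels = 2L, seed = 31L)
  expect_identical(sensor_spec(silent), sensor_spec(NULL))

  # broadband source spreads power across the passband
  bb_src <- make_emi("broadband", 200, band = c(p$larmor_frequency - 2e3,
                                                p$larmor_frequency + 2e3),
                     n_channels = 2L, seed = 32L)
  spec_bb <- sensor_spec(bb_src)
  in_band <- abs(freqs) <= 2e3
  expect_gt(sum(spec_bb[in_band]^2) / sum(spec_bb^2), 0.9)
  expect_lt(max(spec_bb^2) / sum(spec_bb^2), 0.5)   # no single dominating line
})

test_that("the digitizer buffer bound is enforced", {
  expect_silent(mrconsole:::check_rx_buffer(512e6, 1L, 512e6))
  expect_error(mrconsole:::check_rx_buffer(512e6 + 1, 1L, 512e6), "buffer")
  expect_silent(mrconsole:::check_rx_buffer(64e6, 8L, 512e6))
  expect_error(mrconsole:::check_rx_buffer(64e6 + 1, 8L, 512e6), "buffer")

  # a virtual scanner with a small buffer rejects an over-long gate
  p <- desk_params(rx_buffer_capacity = 100)
  u <- unroll_sequence(make_fid(readout_bandwidth = 5e3, adc_duration = 2e-3), p)
  expect_error(simulate_acquisition(u, make_phantom("point"), p), "buffer")
})

test_that("receive quantization overflow is an error, not a clip", {
  p <- desk_params(output_full_scale = 100)
  u <- unroll_sequence(make_fid(readout_bandwidth = 5e3, adc_duration = 2e-3,
                                flip_amplitude = 0), p)
  ph <- make_phantom("point", t2 = 1)
  emi <- make_emi("tone", 5000, frequency = 21e3, n_channels = 1L, seed = 1L)
  expect_error(simulate_acquisition(u, ph, p, emi = list(emi)),
               "overflow")
})
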