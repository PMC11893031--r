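test_that("unrolled sample counts equal duration times sample rate", {
  p <- desk_params()
  for (s in list(make_fid(readout_bandwidth = 5e3, adc_duration = 2e-3),
                 make_monitoring(readout_bandwidth = 5e3),
                 make_tse(desk_tse_protocol(etl = 4L, n = 8L), dims = 2))) {
    u <- unroll_sequence(s, p)
    expect_identical(u$total_samples,
                     as.integer(round(sequence_duration(s) * p$raw_sample_rate)))
    expect_true(all(vapply(u$frames, length, integer(1)) %% 4L == 0L))
    if (nrow(u$gates))
      expect_true(all(u$gates >= 0 & u$gates <= u$total_samples))
  }
})

test_that("trapezoid flat top scales to millivolts like the scalar oracle", {
  scaling <- 37.5
  p <- desk_params(gradient_scaling = c(scaling, 50, 50))
  blk <- seq_block(4e-3, gx = trap_event(80, 2e-4, 3.2e-3, 2e-4, delay = 2e-4))
  u <- unroll_sequence(seq_def(blocks = list(blk)), p)
  gx_codes <- mrconsole:::unrolled_matrix(u)[2, ]
  flat <- mrconsole:::code15_to_mv(mrconsole:::split_digital(gx_codes)$amplitude,
                                   p$output_full_scale)
  # scalar hand computation: quantize(80 kHz/m * scaling mV per kHz/m)
  expected <- round(80 * scaling / p$output_full_scale * 2^14) *
    p$output_full_scale / 2^14
  # flat top spans [delay+rise, delay+rise+flat)
  i <- seq(from = 2e-4 * 1e5 + 2e-4 * 1e5 + 1, length.out = 3.2e-3 * 1e5)
  expect_equal(unique(flat[i]), expected)
  expect_equal(expected, 80 * scaling, tolerance = 1e-3)
})

test_that("gradient scaling is linear in amplitude with zero offset", {
  p <- desk_params()
  mk <- function(a) {
    blk <- seq_block(2e-3, gy = trap_event(a, 2e-4, 1.6e-3, 2e-4))
    u <- unroll_sequence(seq_def(blocks = list(blk)), p)
    codes <- mrconsole:::split_digital(mrconsole:::unrolled_matrix(u)[3, ])$amplitude
    max(abs(codes))
  }
  one <- mk(40)
  two <- mk(80)
  expect_lte(abs(two - 2 * one), 1)   # equality up to one quantization step
})

test_that("RF carrier phase is globally coherent across blocks", {
  p <- desk_params()
  # two abutting RF blocks holding a continuous constant envelope
  blocks <- list(
    seq_block(1e-3, rf = rf_event(100, 1e-3)),
    seq_block(1e-3, rf = rf_event(100, 1e-3))
  )
  u <- unroll_sequence(seq_def(blocks = blocks), p)
  rf <- mrconsole:::code16_to_mv(mrconsole:::unrolled_matrix(u)[1, ],
                                 p$output_full_scale)
  t_abs <- (seq_len(u$total_samples) - 1) / p$raw_sample_rate
  reference <- Re(100 * p$b1_scaling * exp(2i * pi * p$larmor_frequency * t_abs))
  # no phase discontinuity at the block boundary: the whole waveform matches
  # one absolute-time carrier to within quantization
  expect_lt(max(abs(rf - reference)), p$output_full_scale / 2^15)
})

test_that("digital gates are asserted over their events", {
  p <- desk_params()
  fid <- make_fid(rf_duration = 4e-4, adc_duration = 2e-3,
                  readout_bandwidth = 5e3, dead_time = 1e-3,
                  lead_delay = 1e-3, flip_amplitude = 0)
  u <- unroll_sequence(fid, p, rf_lead = 1e-4, rf_lag = 0)
  gw <- mrconsole:::unrolled_gradients(u, p)
  fs <- p$raw_sample_rate

  # zero-amplitude sequence: every amplitude code is zero...
  m <- mrconsole:::unrolled_matrix(u)
  expect_true(all(mrconsole:::split_digital(m[2, ])$amplitude == 0))
  expect_true(all(mrconsole:::split_digital(m[3, ])$amplitude == 0))
  expect_true(all(m[1, ] == 0))
  # ...but the ADC gate bit is still asserted exactly over the ADC event
  adc_on <- which(gw$adc_gate == 1L)
  expect_equal(range(adc_on),
               unname(c(u$gates[1, "start"] + 1L, u$gates[1, "stop"])))
  # RF-unblank opens rf_lead ahead of the pulse
  rf_on <- which(gw$rf_unblank == 1L)
  expect_equal(min(rf_on), (1e-3 - 1e-4) * fs + 1)
  expect_equal(max(rf_on), (1e-3 + 4e-4) * fs)
  # phase reference bit follows the sign of the carrier cosine
  t_abs <- (seq_len(u$total_samples) - 1) / fs
  expect_identical(gw$phase_ref,
                   as.integer(cos(2 * pi * p$larmor_frequency * t_abs) >= 0))
})

test_that("overflow and off-raster durations are hard errors", {
  p <- desk_params()
  big <- seq_def(blocks = list(
    seq_block(1e-3, gx = trap_event(500, 2e-4, 6e-4, 2e-4))))  # 25 V >> full scale
  expect_error(unroll_sequence(big, p), "overflow")
  odd <- seq_def(blocks = list(seq_block(1.05e-5)),
                 definitions = list(BlockDurationRaster = 1.05e-5))
  expect_error(unroll_sequence(odd, p), "sample period")
})
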