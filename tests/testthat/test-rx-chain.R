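test_that("gate assembly derives sample counts from timestamp differences", {
  p <- desk_params()
  u <- unroll_sequence(make_fid(readout_bandwidth = 5e3, adc_duration = 4e-3), p)
  raw <- simulate_acquisition(u, make_phantom("point"), p, signal_scale = 10)
  blocks <- assemble_gates(raw)
  expect_length(blocks, 1L)
  # 4 ms gate at 100 kS/s: duration x rate raw samples per channel
  expect_identical(ncol(blocks[[1]]), 400L)

  corrupt <- raw
  corrupt$blocks[[1]] <- corrupt$blocks[[1]][, -1, drop = FALSE]
  expect_error(assemble_gates(corrupt), "timestamps imply")
  swapped <- raw
  swapped$timestamps <- swapped$timestamps[, c(2, 1), drop = FALSE]
  colnames(swapped$timestamps) <- c("start", "stop")
  expect_error(assemble_gates(swapped), "exceed")
})

test_that("phase-reference separation inverts the simulator packing", {
  fs_mv <- 3000
  set.seed(8)
  amp <- as.integer(sample(-16383:16383, 512, replace = TRUE))
  bits <- as.integer(sample(0:1, 512, replace = TRUE))
  blk <- rbind(pack_digital(amp, bits))
  sp <- split_phase_reference(blk, fs_mv)
  expect_identical(sp$reference, bits)
  expect_equal(sp$analog[1, ], amp * fs_mv / 2^14, tolerance = 1e-12)
  # trivial cases: packed (0, bit = 1) and the full-scale code
  sp0 <- split_phase_reference(rbind(pack_digital(c(0L, 16383L), c(1L, 0L))),
                               fs_mv)
  expect_equal(sp0$analog[1, 1], 0)
  expect_equal(sp0$analog[1, 2], 16383 / 16384 * fs_mv)
  expect_identical(sp0$reference, c(1L, 0L))
})

test_that("demodulation meets the amplitude convention and decimation identity", {
  p <- desk_params()
  R <- decimation_factor(p)
  expect_identical(R * p$receive_bandwidth, p$raw_sample_rate)

  n <- 1280
  tau <- (seq_len(n) - 1) / p$raw_sample_rate
  f0 <- p$larmor_frequency
  A <- 123
  carrier <- A * cos(2 * pi * f0 * tau)
  ref <- as.integer(cos(2 * pi * f0 * tau) >= 0)
  bb <- demodulate_decimate(carrier, ref, p)
  expect_identical(ncol(bb), as.integer(floor(n / R)))
  expect_equal(attr(bb, "dwell"), 1 / p$receive_bandwidth)
  centre <- 20:45
  expect_lt(max(abs(Mod(bb[1, centre]) - A)) / A, 0.01)  # within 1 percent

  # carrier at f0 + delta demodulates to a baseband tone at delta
  delta <- 1200
  sig <- A * cos(2 * pi * (f0 + delta) * tau)
  bb2 <- demodulate_decimate(sig, ref, p)[1, ]
  spec <- Mod(stats::fft(bb2))
  n_out <- length(bb2)
  freqs <- (seq_len(n_out) - 1) * p$receive_bandwidth / n_out
  freqs[freqs >= p$receive_bandwidth / 2] <-
    freqs[freqs >= p$receive_bandwidth / 2] - p$receive_bandwidth
  expect_lt(abs(freqs[which.max(spec)] - delta), p$receive_bandwidth / n_out)

  bad <- acq_params(21300, receive_bandwidth = 5e3, raw_sample_rate = 1e5)
  bad$receive_bandwidth <- 5100            # bypass the constructor check
  expect_error(demodulate_decimate(carrier, ref, bad), "not a positive integer")
})

test_that("a symmetric echo lands on the central readout sample", {
  p <- desk_params()
  R <- decimation_factor(p)
  n <- 640
  tau <- (seq_len(n) - 1) / p$raw_sample_rate
  centre_t <- (n / 2) / p$raw_sample_rate
  envelope <- exp(-((tau - centre_t) / 4e-4)^2)
  sig <- 100 * envelope * cos(2 * pi * p$larmor_frequency * tau)
  ref <- as.integer(cos(2 * pi * p$larmor_frequency * tau) >= 0)
  bb <- demodulate_decimate(sig, ref, p)[1, ]
  expect_equal(which.max(Mod(bb)), length(bb) / 2 + 1)
})

test_that("inter-gate phase is coherent through the reference lock", {
  # the same physical signal acquired in two gates at different absolute
  # times demodulates to the same baseband
  p <- desk_params()
  blocks <- list(
    seq_block(2e-4, rf = rf_event(0.25 / 2e-4, 2e-4)),
    seq_block(3.2e-3, adc = adc_event(8, 2e-4, delay = 1.6e-3)),
    seq_block(2.7e-3, adc = adc_event(8, 2e-4, delay = 1.1e-3)))
  u <- unroll_sequence(seq_def(blocks = blocks), p)
  ph <- make_phantom("point", t2 = 1e6)   # no decay, no off-resonance
  raw <- simulate_acquisition(u, ph, p, signal_scale = 100, seed = 1)
  ks <- receive_chain(raw, p)
  g1 <- ks$data[1, 1, 1, ]
  g2 <- ks$data[1, 1, 2, ]
  expect_lt(max(Mod(g1 - g2)) / max(Mod(g1)), 0.02)
})

test_that("the decimation filter does not amplify in-band energy", {
  h <- mrconsole:::rx_fir(20L)
  H <- Mod(stats::fft(c(h, rep(0, 4096 - length(h)))))
  expect_lt(max(H), 1.01)
})

test_that("k-space sorting honours the encode table and keeps raw data", {
  gates <- lapply(1:6, function(g) matrix(complex(real = g, imaginary = -g),
                                          nrow = 1, ncol = 4))
  tab <- data.frame(gate = 1:6, enc = c(4L, 2L, 6L, 1L, 5L, 3L))
  ks <- sort_kspace(gates, tab)
  expect_identical(dim(ks$data), c(1L, 1L, 6L, 4L))
  for (r in 1:6)
    expect_equal(ks$data[1, 1, tab$enc[r], 1], gates[[r]][1, 1])
  expect_identical(ks$unsorted, gates)
  # inverse permutation restores chronological order
  restored <- lapply(seq_len(6), function(e)
    ks$data[1, 1, tab$enc[match(e, tab$gate)], , drop = TRUE])
  expect_equal(do.call(rbind, restored),
               do.call(rbind, lapply(gates, as.vector)))

  expect_error(sort_kspace(gates, tab[1:5, ]), "encode table")
  single <- sort_kspace(gates[1], NULL)
  expect_identical(dim(single$data), c(1L, 1L, 1L, 4L))

  # averages are averaged on demand
  ks2 <- sort_kspace(c(gates, lapply(gates, function(g) g + 2)),
                     tab, averages = 2L, combine = TRUE)
  expect_identical(dim(ks2$data)[1], 1L)
  expect_equal(ks2$data[1, 1, tab$enc[1], 1], gates[[1]][1, 1] + 1)
})
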