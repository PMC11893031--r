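# Shared desk-scale virtual scanner configuration.
#
# The study conditions are scaled down from the hardware's 20 MS/s / 2 MHz
# operating point to a 100 kS/s raster with a 21.3 kHz carrier so whole
# turbo-spin-echo acquisitions simulate in seconds: the decimation-factor,
# carrier-coherence and gating arithmetic are identical at any rate, and the
# carrier is deliberately incommensurate with the raster so phase-reference
# extraction is exercised without harmonic aliasing.

desk_params <- function(num_rx_channels = 1L, ...) {
  defaults <- list(larmor_frequency = 21300, receive_bandwidth = 5e3,
                   raw_sample_rate = 1e5, output_full_scale = 12000,
                   gradient_scaling = c(50, 50, 50),
                   num_rx_channels = num_rx_channels)
  do.call(acq_params, utils::modifyList(defaults, list(...)))
}

desk_tse_protocol <- function(etl = 8L, n = 32L, tr = 0.5, dummy_shots = 2L,
                              ...) {
  protocol_params(te = 16e-3, tr = tr, etl = etl,
                  fov = c(0.12, 0.12, 0.12), matrix = c(n, n, 1L),
                  readout_bandwidth = 5e3, rf_duration = 2e-4,
                  rise_time = 2e-4, pe_duration = 1e-3,
                  dummy_shots = dummy_shots, ...)
}

# Memoized heavy fixtures (computed once per test run).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# A full 2D TSE sphere acquisition, optionally with tone EMI on 4 channels.
desk_tse_acquisition <- function(with_emi = FALSE) {
  key <- if (with_emi) "tse_emi" else "tse_clean"
  fixture(key, {
    p <- desk_params(num_rx_channels = if (with_emi) 4L else 1L)
    pp <- desk_tse_protocol()
    s <- make_tse(pp, dims = 2)
    u <- unroll_sequence(s, p)
    ph <- make_phantom("sphere", n_spins = 600, extent = 0.07, t2 = 0.15,
                       t1 = 0.3)
    emi <- if (with_emi)
      list(make_emi("tone", amplitude = 300,
                    frequency = p$larmor_frequency + 1700,
                    n_channels = 4L, seed = 11L))
    else list()
    raw <- simulate_acquisition(u, ph, p, emi = emi, signal_scale = 3,
                                seed = 7L, noise_sd = 0.3)
    ks <- receive_chain(raw, p, encode_table = s$metadata$encode_table)
    list(params = p, protocol = pp, seq = s, unrolled = u, phantom = ph,
         raw = raw, kspace = ks)
  })
}

# centroid and equivalent diameter of the bright disc in a magnitude image
disc_geometry <- function(mag, threshold = 0.25) {
  mask <- mag > threshold * max(mag)
  list(centroid = c(mean(row(mag)[mask]), mean(col(mag)[mask])),
       diameter = 2 * sqrt(sum(mask) / pi))
}
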