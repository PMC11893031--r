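#' Virtual scanner: simulate an acquisition from an unrolled sequence
#'
#' Replaces the transmit/receive hardware. The compiled sequence is executed
#' on an isochromat ensemble with a hard-pulse Bloch model: during RF
#' activity the magnetization is rotated chunk-wise on an internal raster,
#' with off-resonance/gradient precession split around each rotation; between
#' pulses the transverse magnetization evolves in closed form from the
#' accumulated gradient phase `2*pi*(sum_axis g_axis(t) r_axis +
#' off_resonance)*t` (gradients in kHz/m are read back from the packed
#' 16-bit gradient codes via the inverse scaling) with T2 decay and T1
#' recovery of the longitudinal component. The MR channel records the real part of the summed transverse
#' magnetization modulated at the Larmor frequency, sampled at the raw rate
#' inside the ADC gates; interference sources are convolved with their
#' per-channel coupling kernels and added (sensor channels receive EMI only,
#' the MR channel receives signal plus EMI leakage); white Gaussian noise of
#' `noise_sd` mV is added per channel; the phase-reference square wave at
#' the Larmor frequency is packed into the digital bit of channel 1; and all
#' channels are quantized to 16-bit codes. Timestamps equal the ADC gate
#' boundaries of the unrolled sequence. Identical seeds give identical
#' output.
#'
#' @param unrolled an `unrolled_seq` from [unroll_sequence()]; must validate
#'   against `params`.
#' @param phantom a [make_phantom()] object.
#' @param params the [acq_params()] the sequence was compiled for.
#' @param emi list of [make_emi()] sources.
#' @param noise_sd per-channel Gaussian noise standard deviation in mV.
#' @param seed RNG seed; the simulation is a pure function of its inputs and
#'   this seed.
#' @param channel_roles character vector of channel roles, one of `"mr"`,
#'   `"emi"`, `"monitor"`; defaults to channel 1 = `"mr"`, rest `"emi"`.
#' @param tx_efficiency virtual transmit coil efficiency in mV per Hz of
#'   nutation: the spins see `envelope_mV / tx_efficiency` Hz.
#' @param signal_scale receive scale in mV per unit transverse magnetization.
#' @param dt_internal internal raster for hard-pulse rotations, s.
#' @param return_analog also return the un-quantized analog mV waveforms per
#'   gate (`$analog`), e.g. to verify superposition properties.
#' @return An object of class `raw_acq`: per-gate 16-bit sample blocks
#'   (`blocks`, each channels x samples), `timestamps` (start/stop raw
#'   sample offsets per gate), `sample_rate`, `channel_roles`, `full_scale`.
#' @export
simulate_acquisition <- function(unrolled, phantom, params, emi = list(),
                                 noise_sd = 0, seed = 1L,
                                 channel_roles = NULL,
                                 tx_efficiency = 1, signal_scale = 1,
                                 dt_internal = 1e-5,
                                 return_analog = FALSE) {
  stopifnot(inherits(unrolled, "unrolled_seq"), inherits(phantom, "phantom"),
            inherits(params, "acq_params"))
  if (!validate_unrolled(unrolled, params))
    stopf("unrolled sequence was not compiled for these acquisition parameters (fingerprint mismatch)")
  if (inherits(emi, "emi_source")) emi <- list(emi)

  nch <- params$num_rx_channels
  if (is.null(channel_roles))
    channel_roles <- c("mr", rep("emi", nch - 1L))
  stopifnot(length(channel_roles) == nch)

  gates <- unrolled$gates
  n_gates <- nrow(gates)
  gate_len <- if (n_gates) as.integer(gates[, "stop"] - gates[, "start"]) else integer(0)
  check_rx_buffer(gate_len, nch, params$rx_buffer_capacity)

  fs <- unrolled$sample_rate
  dt <- 1 / fs
  f0 <- params$larmor_frequency
  set.seed(seed)

  # gate-sample magnetization (complex, per gate)
  m_gate <- bloch_run(unrolled, phantom, params, tx_efficiency, dt_internal)

  analog <- vector("list", n_gates)
  blocks <- vector("list", n_gates)
  for (g in seq_len(n_gates)) {
    len <- gate_len[g]
    idx <- gates[g, "start"] + seq_len(len)      # 1-based raw sample indices
    t_abs <- (idx - 1) * dt
    mr_raw <- Re(m_gate[[g]] * signal_scale * exp(2i * pi * f0 * t_abs))

    ch <- matrix(0, nrow = nch, ncol = len)
    ch[channel_roles == "mr", ] <- rep(mr_raw, each = sum(channel_roles == "mr"))
    for (src in emi) {
      L <- ncol(src$kernels)
      t_pad <- (gates[g, "start"] - (L - 1) + seq_len(len + L - 1L) - 1) * dt
      a <- emi_analytic(src, t_pad, fs, gate_id = g)
      for (c_i in seq_len(min(nch, nrow(src$kernels)))) {
        y <- conv_causal(a, src$kernels[c_i, ])
        ch[c_i, ] <- ch[c_i, ] + Re(y[(L - 1L) + seq_len(len)])
      }
    }
    if (noise_sd > 0)
      ch <- ch + matrix(rnorm(nch * len, sd = noise_sd), nrow = nch)
    if (return_analog) analog[[g]] <- ch

    ref_bit <- as.integer(cos(2 * pi * f0 * t_abs) >= 0)
    blk <- matrix(0L, nrow = nch, ncol = len)
    for (c_i in seq_len(nch)) {
      amp <- mv_to_code15(ch[c_i, ], params$output_full_scale,
                          what = sprintf("receive channel %d", c_i))
      bits <- if (c_i == 1L) ref_bit else integer(len)
      blk[c_i, ] <- pack_digital(amp, bits)
    }
    blocks[[g]] <- blk
  }

  out <- structure(list(
    blocks = blocks,
    timestamps = gates,
    sample_rate = fs,
    channel_roles = channel_roles,
    num_channels = nch,
    full_scale = params$output_full_scale,
    seed = as.integer(seed)
  ), class = "raw_acq")
  if (return_analog) out$analog <- analog
  out
}

#' @export
print.raw_acq <- function(x, ...) {
  cat(sprintf("<raw_acq> %d gates, %d channels (%s) at %g MS/s\n",
              length(x$blocks), x$num_channels,
              paste(x$channel_roles, collapse = ","), x$sample_rate / 1e6))
  invisible(x)
}

# Enforce the digitizer buffer bound: all gated samples, summed over the
# active channels, must fit the on-board memory because transfer only starts
# once the closing timestamp registers.
check_rx_buffer <- function(gate_lengths, n_channels, capacity) {
  total <- sum(as.numeric(gate_lengths)) * n_channels
  if (total > capacity)
    stopf(paste0("ADC gates require %.0f samples across %d channels, ",
                 "exceeding the %.0f-sample digitizer buffer"),
          total, n_channels, capacity)
  invisible(total)
}

# Run the isochromat model over the full timeline; returns a list of complex
# summed-magnetization vectors, one per ADC gate (rotating-frame baseband).
bloch_run <- function(unrolled, phantom, params, tx_efficiency, dt_internal) {
  fs <- unrolled$sample_rate
  dt <- 1 / fs
  N <- unrolled$total_samples
  gates <- unrolled$gates
  n_gates <- nrow(gates)

  gw <- unrolled_gradients(unrolled, params)     # kHz/m per axis
  # cumulative gradient integrals at sample boundaries; Gint[k] = integral
  # of g over [0, (k-1)*dt), so sample k's accrued phase uses Gint[k]
  gint <- lapply(gw[c("x", "y", "z")], function(g) c(0, cumsum(g)) * dt)

  env <- unrolled$rf_envelope                    # complex mV
  active <- Mod(env) > 0
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rf_runs <- cbind(starts[runs$values], ends[runs$values])

  pos <- phantom$pos
  n_spin <- nrow(pos)
  off <- phantom$off_resonance
  inv_t2 <- 1 / phantom$t2
  inv_t1 <- 1 / (phantom$t1 %||% rep(Inf, n_spin))
  m0 <- phantom$magnitude
  # spin response matrix: phase per (elapsed time, gradient integral) row
  B <- rbind(2 * pi * off, 2 * pi * 1000 * t(pos))  # 4 x n_spin

  m <- complex(n_spin)
  mz <- phantom$magnitude
  state_idx <- 1L      # state is defined at time (state_idx - 1) * dt

  m_gate <- lapply(seq_len(n_gates), function(g)
    complex(gates[g, "stop"] - gates[g, "start"]))

  # free evolution from the current state to sample index `target`,
  # evaluating the summed transverse magnetization at gate samples passed on
  # the way
  free_to <- function(target) {
    if (target < state_idx) stopf("internal: non-monotone timeline")
    if (n_gates) {
      for (g in seq_len(n_gates)) {
        i0 <- gates[g, "start"] + 1L
        i1 <- gates[g, "stop"]
        lo <- max(i0, state_idx)
        hi <- min(i1, target)
        if (lo > hi) next
        v <- lo:hi
        P <- cbind((v - state_idx) * dt,
                   gint$x[v] - gint$x[state_idx],
                   gint$y[v] - gint$y[state_idx],
                   gint$z[v] - gint$z[state_idx])
        E <- exp(1i * (P %*% B) - outer(P[, 1], inv_t2))
        m_gate[[g]][v - i0 + 1L] <<- as.vector(E %*% m)
      }
    }
    if (target > state_idx) {
      dtv <- (target - state_idx) * dt
      ph <- dtv * B[1, ] +
        (gint$x[target] - gint$x[state_idx]) * B[2, ] +
        (gint$y[target] - gint$y[state_idx]) * B[3, ] +
        (gint$z[target] - gint$z[state_idx]) * B[4, ]
      m <<- m * exp(1i * ph - dtv * inv_t2)
      mz <<- m0 + (mz - m0) * exp(-dtv * inv_t1)
      state_idx <<- target
    }
  }

  chunk <- max(1L, as.integer(round(dt_internal * fs)))
  for (r in seq_len(nrow(rf_runs))) {
    a <- rf_runs[r, 1]; b <- rf_runs[r, 2]
    free_to(a)
    k <- a
    while (k <= b) {
      k2 <- min(k + chunk - 1L, b)
      n_sub <- k2 - k + 1L
      tau <- n_sub * dt
      b1 <- mean(env[k:k2]) / tx_efficiency          # Hz, rotating frame
      ph_free <- tau * B[1, ] +
        (gint$x[k2 + 1L] - gint$x[k]) * B[2, ] +
        (gint$y[k2 + 1L] - gint$y[k]) * B[3, ] +
        (gint$z[k2 + 1L] - gint$z[k]) * B[4, ]
      half <- exp(1i * ph_free / 2)
      m <- m * half
      theta <- 2 * pi * Mod(b1) * tau
      phi <- Arg(b1)
      if (theta != 0) {
        c2 <- cos(theta / 2)^2
        s2 <- sin(theta / 2)^2
        st <- sin(theta)
        m_new <- m * c2 + Conj(m) * exp(2i * phi) * s2 -
          1i * exp(1i * phi) * mz * st
        mz <- mz * cos(theta) + Im(m * exp(-1i * phi)) * st
        m <- m_new
      }
      m <- m * half * exp(-tau * inv_t2)
      mz <- m0 + (mz - m0) * exp(-tau * inv_t1)
      k <- k2 + 1L
    }
    state_idx <- b + 1L
  }
  free_to(N)
  m_gate
}
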