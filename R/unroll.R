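#' Compile a sequence into hardware-ready interleaved 16-bit waveforms
#'
#' Unrolls a [seq_def()] onto the raw converter raster: gradient events are
#' interpolated (trapezoids piecewise-linearly, arbitrary gradients by linear
#' interpolation), scaled from kHz/m to mV by the per-axis gradient scaling
#' and shifted by the static shim offset; the RF envelope is scaled from Hz
#' to mV by the B1 scaling and digitally modulated with the Larmor frequency,
#' with a globally coherent carrier phase (`2*pi*f0*t` at absolute time `t`,
#' continuous across blocks). Digital control signals — the RF-unblank gate
#' (with configurable lead/lag), the ADC gate and a phase-reference square
#' wave at the Larmor frequency — are packed into the least-significant bit
#' of the gradient channels (see [pack_digital()]), reducing their amplitude
#' precision from 16 to 15 bits. Any amplitude outside the representable
#' range is a hard error; waveforms are never clipped silently.
#'
#' @param seq a [seq_def()] object.
#' @param params an [acq_params()] object.
#' @param bit_map named character vector mapping digital signals to the
#'   gradient channel whose packed bit carries them.
#' @param rf_lead,rf_lag RF-unblank lead/lag around each RF event, seconds.
#' @return An object of class `unrolled_seq` with elements
#'   \describe{
#'     \item{frames}{list of per-block integer vectors of interleaved 16-bit
#'       codes in fixed channel order (RF, Gx, Gy, Gz); each length is a
#'       multiple of 4.}
#'     \item{bit_map}{the digital-signal-to-channel assignment.}
#'     \item{sample_rate}{raw sample rate, samples/s.}
#'     \item{total_samples}{total per-channel sample count,
#'       `round(duration * sample_rate)`.}
#'     \item{gates}{integer matrix of ADC gate boundaries, columns `start`
#'       and `stop`, as 0-based raw sample offsets.}
#'     \item{fingerprint}{fingerprint of `params`.}
#'     \item{rf_envelope}{complex rotating-frame RF envelope in mV at the
#'       raw raster, carried alongside the frames for virtual backends.}
#'   }
#' @examples
#' p <- acq_params(larmor_frequency = 20e3, receive_bandwidth = 5e3,
#'                 raw_sample_rate = 100e3)
#' fid <- make_fid(rf_duration = 2e-4, adc_duration = 2e-3,
#'                 readout_bandwidth = 5e3)
#' u <- unroll_sequence(fid, p)
#' u$total_samples
#' @export
unroll_sequence <- function(seq, params,
                            bit_map = c(rf_unblank = "gx", adc_gate = "gy",
                                        phase_ref = "gz"),
                            rf_lead = 10e-6, rf_lag = 0) {
  stopifnot(inherits(seq, "seq_def"), inherits(params, "acq_params"))
  if (!all(sort(names(bit_map)) == c("adc_gate", "phase_ref", "rf_unblank")) ||
      !all(bit_map %in% c("gx", "gy", "gz")) || anyDuplicated(bit_map))
    stopf("bit_map must assign rf_unblank, adc_gate and phase_ref to distinct gradient channels")

  fs <- params$raw_sample_rate
  dt <- 1 / fs
  fsc <- params$output_full_scale
  f0 <- params$larmor_frequency

  n_blocks <- length(seq$blocks)
  n_per_block <- integer(n_blocks)
  for (i in seq_len(n_blocks)) {
    nb <- seq$blocks[[i]]$duration * fs
    n_per_block[i] <- as.integer(round(nb))
    if (abs(nb - n_per_block[i]) > 1e-6)
      stopf("block %d duration %.9g s is not a multiple of the sample period %.3g s",
            i, seq$blocks[[i]]$duration, dt)
  }
  offsets <- c(0L, cumsum(n_per_block))
  total <- offsets[n_blocks + 1L]

  frames <- vector("list", n_blocks)
  rf_env_mv <- complex(total)
  gates <- NULL

  for (i in seq_len(n_blocks)) {
    b <- seq$blocks[[i]]
    n <- n_per_block[i]
    if (n == 0L) { frames[[i]] <- integer(0); next }
    t_loc <- (seq_len(n) - 1) * dt
    t_abs <- (offsets[i] + seq_len(n) - 1) * dt

    env <- eval_rf_envelope(b$rf, t_loc) * params$b1_scaling   # complex mV
    rf_wave <- Re(env * exp(2i * pi * f0 * t_abs))
    rf_codes <- mv_to_code16(rf_wave, fsc,
                             what = sprintf("block %d RF", i))
    rf_env_mv[offsets[i] + seq_len(n)] <- env

    bits <- list(
      rf_unblank = integer(n), adc_gate = integer(n),
      phase_ref = as.integer(cos(2 * pi * f0 * t_abs) >= 0)
    )
    if (!is.null(b$rf)) {
      t0 <- b$rf$delay - rf_lead
      t1 <- b$rf$delay + b$rf$duration + rf_lag
      bits$rf_unblank[t_loc >= t0 & t_loc < t1] <- 1L
    }
    if (!is.null(b$adc)) {
      a0 <- b$adc$delay
      a1 <- b$adc$delay + b$adc$num * b$adc$dwell
      bits$adc_gate[t_loc >= a0 & t_loc < a1] <- 1L
      g_start <- as.integer(offsets[i] + round(a0 * fs))
      g_stop <- as.integer(g_start + round((a1 - a0) * fs))
      gates <- rbind(gates, c(g_start, g_stop))
    }

    axis_codes <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
      ia <- match(ax, c("x", "y", "z"))
      g <- eval_gradient(b$grad[[ax]], t_loc)                  # kHz/m
      mv <- g * params$gradient_scaling[ia] + params$gradient_offset[ia]
      amp <- mv_to_code15(mv, fsc, what = sprintf("block %d G%s", i, ax))
      sig <- names(bit_map)[match(paste0("g", ax), bit_map)]
      pack_digital(amp, bits[[sig]])
    })

    fr <- matrix(0L, nrow = 4L, ncol = n)
    fr[1L, ] <- rf_codes
    fr[2L, ] <- axis_codes$x
    fr[3L, ] <- axis_codes$y
    fr[4L, ] <- axis_codes$z
    frames[[i]] <- as.integer(fr)                              # interleaved
  }

  if (is.null(gates)) gates <- matrix(integer(0), ncol = 2L)
  colnames(gates) <- c("start", "stop")
  structure(list(
    frames = frames,
    bit_map = bit_map,
    sample_rate = fs,
    total_samples = total,
    gates = gates,
    fingerprint = fingerprint(params),
    rf_envelope = rf_env_mv,
    block_samples = n_per_block,
    full_scale = fsc
  ), class = "unrolled_seq")
}

#' @export
print.unrolled_seq <- function(x, ...) {
  cat(sprintf("<unrolled_seq> %d blocks, %d samples/channel at %g MS/s, %d ADC gates\n",
              length(x$frames), x$total_samples, x$sample_rate / 1e6,
              nrow(x$gates)))
  cat(sprintf("  fingerprint %s\n", x$fingerprint))
  invisible(x)
}

#' Validate an unrolled sequence against acquisition parameters
#'
#' `TRUE` iff the fingerprint stored at compile time matches the fingerprint
#' of `params`, i.e. the sequence was compiled for exactly this parameter
#' set.
#'
#' @param unrolled an `unrolled_seq`.
#' @param params an [acq_params()] object.
#' @return Logical scalar.
#' @export
validate_unrolled <- function(unrolled, params) {
  stopifnot(inherits(unrolled, "unrolled_seq"))
  identical(unrolled$fingerprint, fingerprint(params))
}

# De-interleave the frames into a 4 x total_samples integer matrix
# (channel order RF, Gx, Gy, Gz).
unrolled_matrix <- function(unrolled) {
  matrix(unlist(unrolled$frames, use.names = FALSE), nrow = 4L)
}

# Recover the per-axis physical gradient fields in kHz/m (and the digital
# bit streams) from the packed frames via the inverse scaling. The full
# output voltage — commanded waveform plus static shim offset — drives the
# gradient coil, so the offset is part of the field the spins see.
unrolled_gradients <- function(unrolled, params) {
  m <- unrolled_matrix(unrolled)
  out <- list()
  bits <- list()
  for (ax in c("x", "y", "z")) {
    row <- 1L + match(ax, c("x", "y", "z"))
    sp <- split_digital(m[row, ])
    mv <- code15_to_mv(sp$amplitude, unrolled$full_scale)
    ia <- match(ax, c("x", "y", "z"))
    out[[ax]] <- mv / params$gradient_scaling[ia]
    sig <- names(unrolled$bit_map)[match(paste0("g", ax), unrolled$bit_map)]
    bits[[sig]] <- sp$bits
  }
  c(out, bits)
}
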