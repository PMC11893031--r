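#' Virtual scanner backend for calibration routines
#'
#' Wraps a phantom and acquisition parameters into an `acquire` closure that
#' compiles a sequence, runs the virtual scanner and returns the raw
#' acquisition — the same contract a hardware backend would offer, so the
#' calibration routines run unchanged against either.
#'
#' @param phantom a [make_phantom()] object.
#' @param params default [acq_params()].
#' @param emi,noise_sd,seed,... passed to [simulate_acquisition()].
#' @return List of class `mr_backend` with elements `acquire(seq, params)`
#'   and `params`.
#' @export
virtual_backend <- function(phantom, params, emi = list(), noise_sd = 0,
                            seed = 1L, ...) {
  extra <- list(...)
  acquire <- function(seq, params_override = NULL) {
    p <- params_override %||% params
    u <- unroll_sequence(seq, p)
    do.call(simulate_acquisition,
            c(list(unrolled = u, phantom = phantom, params = p, emi = emi,
                   noise_sd = noise_sd, seed = seed), extra))
  }
  structure(list(acquire = acquire, params = params), class = "mr_backend")
}

# Acquire an FID and return the demodulated complex baseband of the MR
# channel (first gate).
acquire_fid_baseband <- function(backend, params = backend$params,
                                 rf_duration = 2e-4, adc_duration = NULL,
                                 flip_amplitude = NULL, dead_time = 1e-3) {
  adc_duration <- adc_duration %||% (64 / params$receive_bandwidth)
  fid <- make_fid(rf_duration = rf_duration, adc_duration = adc_duration,
                  readout_bandwidth = params$receive_bandwidth,
                  dead_time = dead_time, flip_amplitude = flip_amplitude)
  raw <- backend$acquire(fid, params)
  ks <- receive_chain(raw, params)
  structure(ks$data[1, 1, 1, ], dwell = ks$dwell)
}

new_calibration_result <- function(quantity, value, grid, objective,
                                   converged, unit) {
  structure(list(quantity = quantity, value = value, grid = grid,
                 objective = objective, converged = converged, unit = unit),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s = %.6g %s (%s)\n", x$quantity,
              x$value, x$unit,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Find the Larmor frequency from an FID spectrum
#'
#' Acquires an FID, Fourier-transforms the demodulated baseband and locates
#' the magnitude peak with parabolic sub-bin refinement; the result is the
#' demodulation frequency plus the measured offset. Flagged non-converged
#' when the peak does not exceed three times the spectral noise floor
#' (median magnitude).
#'
#' @param backend an acquisition backend (e.g. [virtual_backend()]).
#' @param params acquisition parameters; defaults to the backend's.
#' @param search_span restrict the peak search to +/- `search_span` Hz
#'   around the demodulation frequency; `NULL` searches the full band.
#' @param adc_duration FID gate duration in s.
#' @return A `calibration_result` with the frequency in Hz.
#' @export
find_larmor <- function(backend, params = backend$params, search_span = NULL,
                        adc_duration = NULL) {
  bb <- acquire_fid_baseband(backend, params, adc_duration = adc_duration)
  dwell <- attr(bb, "dwell")
  # zero-pad 8x so the parabolic refinement works on a well-resolved peak
  n <- 8L * length(bb)
  spec <- Mod(stats::fft(c(bb, rep(0i, n - length(bb)))))
  freqs <- (seq_len(n) - 1) / (n * dwell)
  freqs[freqs >= 1 / (2 * dwell)] <- freqs[freqs >= 1 / (2 * dwell)] - 1 / dwell
  in_span <- if (is.null(search_span)) rep(TRUE, n) else abs(freqs) <= search_span
  cand <- which(in_span)
  pk <- cand[which.max(spec[cand])]
  # upper envelope of the noise bins: a real line occupies few bins, so the
  # 95th percentile tracks the noise floor
  floor_level <- stats::quantile(spec, 0.95, names = FALSE)
  converged <- spec[pk] >= 3 * floor_level
  # parabolic sub-bin refinement on the circular spectrum
  lo <- if (pk == 1L) n else pk - 1L
  hi <- if (pk == n) 1L else pk + 1L
  delta <- parabolic_vertex(spec[lo], spec[pk], spec[hi])
  offset <- freqs[pk] + delta / (n * dwell)
  new_calibration_result("larmor_frequency",
                         params$larmor_frequency + offset,
                         freqs, spec, converged, "Hz")
}

#' Calibrate the 90-degree RF amplitude
#'
#' Sweeps the FID excitation amplitude over a grid and selects the amplitude
#' maximizing the magnitude integral of the FID, with quadratic refinement
#' around the grid optimum. A maximum on the grid edge is flagged
#' non-converged.
#'
#' @param backend an acquisition backend.
#' @param amplitude_grid RF amplitudes to probe, in Hz of nutation.
#' @param params acquisition parameters; defaults to the backend's.
#' @param rf_duration excitation pulse duration in s.
#' @return A `calibration_result` with the 90-degree amplitude in Hz.
#' @export
calibrate_rf_amplitude <- function(backend, amplitude_grid,
                                   params = backend$params,
                                   rf_duration = 2e-4) {
  obj <- vapply(amplitude_grid, function(a) {
    bb <- acquire_fid_baseband(backend, params, rf_duration = rf_duration,
                               flip_amplitude = a)
    sum(Mod(bb)) * attr(bb, "dwell")
  }, numeric(1))
  # the objective is periodic in flip angle (|sin|): take the first peak of
  # the sweep (the 90 degree point), not a later equal maximum (e.g. 270)
  n <- length(obj)
  is_peak <- c(FALSE, obj[2:(n - 1)] >= obj[1:(n - 2)] &
                 obj[2:(n - 1)] >= obj[3:n], FALSE)
  cand <- which(is_peak & obj >= 0.95 * max(obj))
  i <- if (length(cand)) cand[1] else which.max(obj)
  edge <- i == 1L || i == length(amplitude_grid)
  value <- amplitude_grid[i]
  if (!edge) {
    delta <- parabolic_vertex(obj[i - 1L], obj[i], obj[i + 1L])
    step_lo <- amplitude_grid[i] - amplitude_grid[i - 1L]
    step_hi <- amplitude_grid[i + 1L] - amplitude_grid[i]
    value <- value + delta * if (delta >= 0) step_hi else step_lo
  }
  new_calibration_result("rf_amplitude_90", value, amplitude_grid, obj,
                         !edge, "Hz")
}

#' Calibrate static first-order (gradient offset) shims
#'
#' Coordinate-wise search over per-axis gradient offset values (mV applied
#' to each gradient coil) maximizing the FID magnitude integral — a linear
#' background gradient dephases the FID, so the integral peaks where the
#' offsets cancel it. Axes are searched in x, y, z order for `n_passes`
#' passes; each axis optimum is refined quadratically. An optimum on a grid
#' edge is flagged non-converged.
#'
#' @param backend an acquisition backend.
#' @param offset_grid numeric vector of offsets (mV) probed on every axis,
#'   or a list of three vectors (x, y, z).
#' @param params acquisition parameters; defaults to the backend's.
#' @param n_passes coordinate passes over the three axes.
#' @param adc_duration FID gate duration in s.
#' @return A `calibration_result`; `value` is the length-3 offset vector
#'   in mV.
#' @export
calibrate_shim <- function(backend, offset_grid, params = backend$params,
                           n_passes = 1L, adc_duration = NULL) {
  if (!is.list(offset_grid)) offset_grid <- list(offset_grid, offset_grid, offset_grid)
  best <- params$gradient_offset
  converged <- TRUE
  objectives <- vector("list", 3L)
  for (pass in seq_len(n_passes)) {
    for (ax in 1:3) {
      grid <- offset_grid[[ax]]
      obj <- vapply(grid, function(o) {
        p <- params
        off <- best; off[ax] <- o
        p$gradient_offset <- off
        bb <- acquire_fid_baseband(backend, p, adc_duration = adc_duration)
        sum(Mod(bb)) * attr(bb, "dwell")
      }, numeric(1))
      i <- which.max(obj)
      edge <- i == 1L || i == length(grid)
      if (edge) converged <- FALSE
      val <- grid[i]
      if (!edge) {
        delta <- parabolic_vertex(obj[i - 1L], obj[i], obj[i + 1L])
        step <- if (delta >= 0) grid[i + 1L] - grid[i] else grid[i] - grid[i - 1L]
        val <- val + delta * step
      }
      best[ax] <- val
      objectives[[ax]] <- obj
    }
  }
  new_calibration_result("gradient_offset", best, offset_grid, objectives,
                         converged, "mV")
}

#' Estimate the gradient chain delay from monitored waveforms
#'
#' Cross-correlates the commanded gradient waveform with the monitored
#' (measured) one and refines the correlation maximum parabolically to
#' sub-sample precision. The result feeds the readout gradient correction
#' time of [protocol_params()].
#'
#' @param commanded,monitored numeric waveforms at the same sampling rate.
#' @param sample_rate sampling rate in samples/s.
#' @param min_correlation normalized correlation required at the peak;
#'   below this the estimate is rejected as unreliable.
#' @return Delay of `monitored` relative to `commanded` in seconds
#'   (positive = monitored lags).
#' @export
estimate_gradient_delay <- function(commanded, monitored, sample_rate,
                                    min_correlation = 0.2) {
  stopifnot(length(commanded) == length(monitored))
  n <- length(commanded)
  x <- commanded
  y <- monitored
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  Y <- stats::fft(c(y, rep(0, nfft - n)))
  r <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  lags <- c(0:(nfft / 2 - 1), -(nfft / 2):-1)
  keep <- abs(lags) <= n - 1L
  r <- r[keep]; lags <- lags[keep]
  norm <- sqrt(sum(x^2) * sum(y^2))
  if (norm == 0 || max(r) / norm < min_correlation)
    stopf("correlation peak %.3f below threshold %.3f: cannot estimate delay",
          if (norm > 0) max(r) / norm else 0, min_correlation)
  i <- which.max(r)
  ord <- order(lags)
  pos <- match(i, ord)
  delta <- 0
  if (pos > 1L && pos < length(ord)) {
    delta <- parabolic_vertex(r[ord[pos - 1L]], r[i], r[ord[pos + 1L]])
  }
  (lags[i] + delta) / sample_rate
}

#' Convert a B0 field shift to a frequency shift
#'
#' Multiplies by the proton gyromagnetic ratio (42.577 MHz/T): a drift of
#' 2.63 microtesla corresponds to about 112 Hz.
#'
#' @param delta_b0 field shift in tesla.
#' @return Frequency shift in Hz.
#' @examples
#' b0_shift_to_frequency(2.63e-6)   # ~112 Hz
#' @export
b0_shift_to_frequency <- function(delta_b0) {
  delta_b0 * GAMMA_BAR_HZ_PER_T
}
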