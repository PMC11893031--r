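#' Acquisition parameters of the console
#'
#' Bundles every scan-time scaling and frequency constant of the data path:
#' the Larmor frequency used for digital modulation and demodulation, the B1
#' scaling that converts an RF envelope amplitude in Hz of nutation to output
#' millivolts, per-axis gradient scalings (the composite of gradient coil
#' efficiency, amplifier gain, gyromagnetic ratio and field-of-view scaling)
#' and static shim offsets, the receive bandwidth, the shared raw converter
#' sampling rate, the receive channel count, the digitizer buffer capacity
#' and the full-scale output voltage of the 16-bit converters.
#'
#' The parameter set has a stable fingerprint (see [fingerprint()]) so a
#' compiled sequence can be validated against the parameters it was compiled
#' for before it is executed.
#'
#' @param larmor_frequency Larmor frequency in Hz; must lie below the Nyquist
#'   frequency `raw_sample_rate / 2`.
#' @param b1_scaling RF scaling in mV per Hz of envelope amplitude.
#' @param gradient_scaling numeric length 3 (x, y, z), mV per kHz/m.
#' @param gradient_offset numeric length 3 (x, y, z), static shim offset in mV.
#' @param receive_bandwidth receive bandwidth in Hz; `raw_sample_rate /
#'   receive_bandwidth` must be a positive integer (the decimation factor).
#' @param raw_sample_rate converter sampling rate in samples/s, shared by the
#'   transmit and receive converters.
#' @param num_rx_channels number of receive channels, 1 to 8.
#' @param rx_buffer_capacity digitizer buffer capacity in samples, summed over
#'   the active channels (default 512e6, i.e. 512 MS on-board memory).
#' @param output_full_scale output voltage in mV corresponding to the maximum
#'   DAC code.
#' @return An object of class `acq_params`.
#' @examples
#' p <- acq_params(larmor_frequency = 2.048e6, receive_bandwidth = 20e3,
#'                 raw_sample_rate = 20e6)
#' decimation_factor(p)
#' @export
acq_params <- function(larmor_frequency,
                       b1_scaling = 1,
                       gradient_scaling = c(50, 50, 50),
                       gradient_offset = c(0, 0, 0),
                       receive_bandwidth = 20e3,
                       raw_sample_rate = 20e6,
                       num_rx_channels = 1L,
                       rx_buffer_capacity = 512e6,
                       output_full_scale = 12000) {
  p <- structure(list(
    larmor_frequency = as.numeric(larmor_frequency),
    b1_scaling = as.numeric(b1_scaling),
    gradient_scaling = as.numeric(gradient_scaling),
    gradient_offset = as.numeric(gradient_offset),
    receive_bandwidth = as.numeric(receive_bandwidth),
    raw_sample_rate = as.numeric(raw_sample_rate),
    num_rx_channels = as.integer(num_rx_channels),
    rx_buffer_capacity = as.numeric(rx_buffer_capacity),
    output_full_scale = as.numeric(output_full_scale)
  ), class = "acq_params")
  validate_acq_params(p)
  p
}

validate_acq_params <- function(p) {
  if (!(p$larmor_frequency > 0 && p$larmor_frequency < p$raw_sample_rate / 2))
    stopf("larmor_frequency must lie in (0, raw_sample_rate/2)")
  if (p$b1_scaling <= 0 || !is.finite(p$b1_scaling))
    stopf("b1_scaling must be positive and finite")
  if (length(p$gradient_scaling) != 3L || any(!is.finite(p$gradient_scaling)) ||
      any(p$gradient_scaling == 0))
    stopf("gradient_scaling must be 3 finite non-zero values (x, y, z)")
  if (length(p$gradient_offset) != 3L || any(!is.finite(p$gradient_offset)))
    stopf("gradient_offset must be 3 finite values (x, y, z)")
  if (any(abs(p$gradient_offset) >= p$output_full_scale))
    stopf("|gradient_offset| must stay below output_full_scale")
  r <- p$raw_sample_rate / p$receive_bandwidth
  if (!is_count(r))
    stopf("raw_sample_rate / receive_bandwidth must be a positive integer (got %g)", r)
  if (!is_count(p$num_rx_channels) || p$num_rx_channels > 8L)
    stopf("num_rx_channels must be an integer in [1, 8]")
  if (p$rx_buffer_capacity <= 0)
    stopf("rx_buffer_capacity must be positive")
  if (p$output_full_scale <= 0)
    stopf("output_full_scale must be positive")
  invisible(p)
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params>\n")
  cat(sprintf("  Larmor frequency : %.6g Hz\n", x$larmor_frequency))
  cat(sprintf("  B1 scaling       : %g mV/Hz\n", x$b1_scaling))
  cat(sprintf("  gradient scaling : %s mV/(kHz/m)\n",
              paste(format(x$gradient_scaling), collapse = ", ")))
  cat(sprintf("  gradient offset  : %s mV\n",
              paste(format(x$gradient_offset), collapse = ", ")))
  cat(sprintf("  bandwidth        : %g Hz (decimation %d at %g MS/s)\n",
              x$receive_bandwidth, decimation_factor(x), x$raw_sample_rate / 1e6))
  cat(sprintf("  rx channels      : %d, buffer %g MS\n",
              x$num_rx_channels, x$rx_buffer_capacity / 1e6))
  cat(sprintf("  fingerprint      : %s\n", fingerprint(x)))
  invisible(x)
}

#' Decimation factor of a parameter set
#'
#' Ratio of the raw converter sampling rate to the receive bandwidth; an exact
#' integer by construction of [acq_params()].
#'
#' @param params an [acq_params()] object.
#' @return Integer decimation factor.
#' @export
decimation_factor <- function(params) {
  as.integer(round(params$raw_sample_rate / params$receive_bandwidth))
}

#' Maximum gated ADC duration permitted by the digitizer buffer
#'
#' The digitizer transfers a gate to host memory only after its closing
#' timestamp, so a single gate (summed over all active channels) must fit the
#' on-board buffer. With the default 512 MS buffer at 20 MS/s this is 25.6 s
#' for one receive channel and 3.2 s for eight.
#'
#' @param params an [acq_params()] object.
#' @param num_channels number of active receive channels; defaults to
#'   `params$num_rx_channels`.
#' @return Maximum ADC gate duration in seconds.
#' @export
max_adc_duration <- function(params, num_channels = params$num_rx_channels) {
  params$rx_buffer_capacity / (params$raw_sample_rate * num_channels)
}

#' Stable fingerprint of an acquisition parameter set
#'
#' Canonical full-precision serialization of every field, hashed with MD5.
#' Equal parameter sets give equal tokens; changing any field (even a 1 Hz
#' frequency shift) changes the token. Compiled sequences carry the
#' fingerprint of the parameters they were compiled for; [validate_unrolled()]
#' compares tokens before execution.
#'
#' @param params an [acq_params()] object.
#' @return A character scalar (32 hex digits).
#' @export
fingerprint <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  canon <- paste(
    vapply(params, function(v) paste(sprintf("%.17g", as.numeric(v)), collapse = ","),
           character(1)),
    collapse = ";")
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(canon, tf, sep = "")
  unname(tools::md5sum(tf))
}
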