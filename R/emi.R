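#' Define an electromagnetic interference source
#'
#' Interference scenarios for the virtual scanner: a constant-frequency tone
#' or band-limited broadband noise, coupled into every receive channel
#' through a per-channel complex finite impulse response (the coupling
#' kernel). Kernels are drawn reproducibly from `seed`, so the same source
#' definition always produces the same interference. Channel 1 (the MR coil)
#' receives the source through its own kernel as well — EMI leaks into the
#' primary coil just as it reaches the sensing coils.
#'
#' @param kind `"tone"` or `"broadband"`.
#' @param amplitude source amplitude in mV.
#' @param frequency tone frequency in Hz (required for `kind = "tone"`).
#' @param band length-2 numeric, band edges `(low, high)` in Hz (required
#'   for `kind = "broadband"`).
#' @param n_channels number of receive channels to couple into.
#' @param seed integer seed for the coupling kernels (and tone phase).
#' @param kernel_length coupling kernel length in taps.
#' @param coupling per-channel coupling strength multiplier; scalar or
#'   length `n_channels`. Channel 1 is the MR coil, so `coupling[1]` sets
#'   the EMI leakage into the primary channel.
#' @return An object of class `emi_source`.
#' @export
make_emi <- function(kind = c("tone", "broadband"), amplitude,
                     frequency = NULL, band = NULL, n_channels = 1L,
                     seed = 1L, kernel_length = 5L, coupling = 1) {
  kind <- match.arg(kind)
  if (kind == "tone" && is.null(frequency))
    stopf("a tone source needs a frequency")
  if (kind == "broadband") {
    if (is.null(band) || length(band) != 2L || band[1] >= band[2])
      stopf("a broadband source needs band = c(low, high) with low < high")
  }
  coupling <- rep_len(coupling, n_channels)
  kernels <- with_seed(seed, {
    k <- matrix(complex(real = rnorm(n_channels * kernel_length),
                        imaginary = rnorm(n_channels * kernel_length)) /
                  sqrt(2 * kernel_length),
                nrow = n_channels)
    k * coupling
  })
  phase0 <- with_seed(seed + 1L, stats::runif(1, 0, 2 * pi))
  if (any(!is.finite(kernels))) stopf("coupling kernels must be finite")
  structure(list(kind = kind, amplitude = amplitude, frequency = frequency,
                 band = band, n_channels = as.integer(n_channels),
                 seed = as.integer(seed), kernels = kernels,
                 phase0 = phase0), class = "emi_source")
}

# Complex analytic interference waveform at absolute times t (s).
# Broadband noise is drawn from a stream keyed on (source seed, gate id) so
# simulations are reproducible and sources superpose linearly.
emi_analytic <- function(src, t, fs, gate_id = 1L) {
  if (src$kind == "tone") {
    src$amplitude * exp(1i * (2 * pi * src$frequency * t + src$phase0))
  } else {
    if (src$band[2] > fs / 2)
      stopf("broadband EMI band edge %g Hz exceeds the Nyquist frequency %g Hz",
            src$band[2], fs / 2)
    n <- length(t)
    fc <- mean(src$band)
    half_bw <- diff(src$band) / 2
    with_seed((src$seed * 1009L + gate_id) %% .Machine$integer.max, {
      x <- complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
      # band-limit the complex baseband noise, then shift to the band centre
      ntaps <- 101L
      h <- signal::fir1(ntaps - 1L, min(0.999, 2 * half_bw / fs))
      h <- h / sum(h)
      xf <- fft_conv(x, h)[(ntaps - 1L) / 2 + seq_len(n)]
      # renormalize to unit power, then scale to the requested amplitude
      p <- sqrt(mean(Mod(xf)^2))
      if (p > 0) xf <- xf / p
      src$amplitude * xf * exp(1i * 2 * pi * fc * t)
    })
  }
}
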