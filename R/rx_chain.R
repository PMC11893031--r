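#' Assemble gated acquisitions into per-gate channel blocks
#'
#' Checks the timestamp pairs of a [simulate_acquisition()] result: each
#' gate's sample count must equal the timestamp difference, and the block
#' shape must match the active channel count. Returns the gate blocks in
#' channel-major layout.
#'
#' @param raw a `raw_acq` object.
#' @return List of integer matrices (channels x samples), one per gate.
#' @export
assemble_gates <- function(raw) {
  stopifnot(inherits(raw, "raw_acq"))
  ts <- raw$timestamps
  if (length(raw$blocks) != nrow(ts))
    stopf("timestamp pairs (%d) do not match gate blocks (%d)",
          nrow(ts), length(raw$blocks))
  for (g in seq_along(raw$blocks)) {
    n <- ts[g, "stop"] - ts[g, "start"]
    if (n <= 0) stopf("gate %d: stop timestamp must exceed start", g)
    if (g > 1 && ts[g, "start"] < ts[g - 1, "stop"])
      stopf("gate %d: timestamps out of chronological order", g)
    blk <- raw$blocks[[g]]
    if (!is.matrix(blk) || nrow(blk) != raw$num_channels || ncol(blk) != n)
      stopf("gate %d: block is %d x %d but timestamps imply %d x %d samples",
            g, NROW(blk), NCOL(blk), raw$num_channels, n)
  }
  raw$blocks
}

#' Separate the phase-reference bit from the analog samples
#'
#' The phase-reference square wave is encoded in the digital bit of
#' channel 1. Clearing the bit and scaling by `full_scale / 2^15` converts
#' the remaining code to floating-point millivolts — the exact inverse of
#' the transmit-side packing.
#'
#' @param gate_block integer matrix (channels x samples) of packed codes.
#' @param full_scale full-scale output in mV.
#' @return List with `analog` (numeric matrix, mV) and `reference`
#'   (integer 0/1 vector from channel 1).
#' @export
split_phase_reference <- function(gate_block, full_scale) {
  stopifnot(is.matrix(gate_block))
  bits <- gate_block %% 2L
  cleared <- gate_block - bits
  analog <- cleared * full_scale / 2^15
  list(analog = analog, reference = as.integer(bits[1L, ]))
}

#' Quadrature demodulation and FIR decimation of a gate
#'
#' Demodulates against a carrier at the Larmor frequency whose phase is
#' locked to the recorded phase reference: the +/-1-mapped reference bit
#' stream is projected onto a complex exponential at `f0` (a least-squares
#' fit of its fundamental), which recovers the absolute carrier phase at the
#' gate start, making demodulation coherent across gates. The demodulated
#' signal is low-pass filtered with a windowed-sinc (Hamming) FIR of length
#' `8 R + 1` (capped at 4001 taps, unit DC gain, cutoff at half the receive
#' bandwidth) and decimated by `R = raw_sample_rate / receive_bandwidth`.
#' The filter group delay is compensated so a symmetric echo at the gate
#' centre lands on the central readout sample. A pure carrier of amplitude
#' A mV demodulates to a complex baseband of magnitude A.
#'
#' @param analog numeric matrix (channels x samples) in mV, or a vector.
#' @param reference integer 0/1 phase-reference stream (from
#'   [split_phase_reference()]); `NULL` falls back to the absolute-time
#'   carrier phase `2 pi f0 t_start` (requires `gate_start_time`).
#' @param params an [acq_params()] object.
#' @param gate_start_time absolute gate start time in s, for the fallback.
#' @return Complex matrix (channels x readout samples) of baseband data,
#'   with attributes `dwell` (s) and `decimation`.
#' @export
demodulate_decimate <- function(analog, reference, params,
                                gate_start_time = NULL) {
  if (is.vector(analog)) analog <- matrix(analog, nrow = 1L)
  R <- params$raw_sample_rate / params$receive_bandwidth
  if (!is_count(R))
    stopf("decimation factor %.6g is not a positive integer", R)
  R <- as.integer(R)
  fs <- params$raw_sample_rate
  f0 <- params$larmor_frequency
  n <- ncol(analog)
  tau <- (seq_len(n) - 1) / fs

  phi <- if (!is.null(reference) && length(unique(reference)) > 1L) {
    Arg(sum((2 * reference - 1) * exp(-2i * pi * f0 * tau)))
  } else if (!is.null(gate_start_time)) {
    (2 * pi * f0 * gate_start_time) %% (2 * pi)
  } else 0

  carrier <- 2 * exp(-1i * (2 * pi * f0 * tau + phi))
  h <- rx_fir(R)
  gd <- (length(h) - 1L) / 2L
  n_out <- floor(n / R)
  pick <- gd + 1L + (seq_len(n_out) - 1L) * R
  out <- matrix(0i, nrow = nrow(analog), ncol = n_out)
  for (c_i in seq_len(nrow(analog))) {
    y <- fft_conv(analog[c_i, ] * carrier, h)
    out[c_i, ] <- y[pick]
  }
  structure(out, dwell = R / fs, decimation = R)
}

# windowed-sinc (Hamming) low-pass decimation filter, unit DC gain
rx_fir <- function(R) {
  len <- min(8L * R + 1L, 4001L)
  if (len %% 2L == 0L) len <- len + 1L
  h <- signal::fir1(len - 1L, 1 / R)
  h / sum(h)
}

#' Sort demodulated gates into k-space order
#'
#' Places chronologically acquired gates at their Cartesian phase-encode
#' positions using the protocol's encode table. The unsorted per-gate data
#' are retained alongside, giving access to the unprocessed view.
#'
#' @param gates list of complex channel x readout matrices (one per gate,
#'   chronological), e.g. from [demodulate_decimate()].
#' @param encode_table data frame with columns `gate` and `enc` (1-based
#'   k-space position of each gate within one average), as produced by
#'   [make_tse()]; `NULL` uses the identity mapping.
#' @param averages number of repetitions; gate count must equal
#'   `averages * encodings`.
#' @param combine combine averages by mean (collapsing the first dimension)?
#' @return Object of class `kspace_data`: `data` is a complex array
#'   `[averages, coils, encodings, readout]`, `unsorted` keeps the input
#'   gate list; `dwell` and `decimation` are carried through when present.
#' @export
sort_kspace <- function(gates, encode_table = NULL, averages = 1L,
                        combine = FALSE) {
  stopifnot(is.list(gates), length(gates) >= 1L)
  n_gates <- length(gates)
  if (n_gates %% averages != 0)
    stopf("%d gates do not divide into %d averages", n_gates, averages)
  per_avg <- n_gates %/% averages
  if (is.null(encode_table))
    encode_table <- data.frame(gate = seq_len(per_avg), enc = seq_len(per_avg))
  if (nrow(encode_table) != per_avg)
    stopf("encode table has %d rows but each average has %d gates",
          nrow(encode_table), per_avg)
  n_coils <- nrow(gates[[1]])
  n_read <- ncol(gates[[1]])
  n_enc <- max(encode_table$enc)
  data <- array(NA_complex_, dim = c(averages, n_coils, n_enc, n_read))
  for (a in seq_len(averages)) {
    for (r in seq_len(per_avg)) {
      g <- gates[[(a - 1L) * per_avg + encode_table$gate[r]]]
      if (nrow(g) != n_coils || ncol(g) != n_read)
        stopf("gate %d has inconsistent shape", (a - 1L) * per_avg + r)
      data[a, , encode_table$enc[r], ] <- g
    }
  }
  ks <- structure(list(
    data = data, unsorted = gates,
    bandwidth = NULL,
    dwell = attr(gates[[1]], "dwell"),
    decimation = attr(gates[[1]], "decimation"),
    encode_table = encode_table
  ), class = "kspace_data")
  if (combine) ks <- combine_averages(ks)
  ks
}

#' Average the repetitions of a k-space data set
#'
#' @param kspace a `kspace_data` object.
#' @return The object with the averages dimension collapsed to 1 (mean).
#' @export
combine_averages <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_data"))
  d <- dim(kspace$data)
  if (d[1] == 1L) return(kspace)
  avg <- array(0i, dim = c(1L, d[2], d[3], d[4]))
  avg[1, , , ] <- colMeans(kspace$data, dims = 1)
  kspace$data <- avg
  kspace
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_data> [%d averages, %d coils, %d encodings, %d readout]\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Run the full receive chain on a raw acquisition
#'
#' Convenience wrapper: [assemble_gates()], [split_phase_reference()] and
#' [demodulate_decimate()] per gate, then [sort_kspace()].
#'
#' @param raw a `raw_acq`.
#' @param params an [acq_params()] object.
#' @param encode_table,averages,combine passed to [sort_kspace()].
#' @return A `kspace_data` object.
#' @export
receive_chain <- function(raw, params, encode_table = NULL, averages = 1L,
                          combine = FALSE) {
  blocks <- assemble_gates(raw)
  fs <- raw$sample_rate
  baseband <- lapply(seq_along(blocks), function(g) {
    sp <- split_phase_reference(blocks[[g]], raw$full_scale)
    demodulate_decimate(sp$analog, sp$reference, params,
                        gate_start_time = raw$timestamps[g, "start"] / fs)
  })
  ks <- sort_kspace(baseband, encode_table, averages, combine)
  ks$bandwidth <- params$receive_bandwidth
  ks
}
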