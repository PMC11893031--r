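#' Pack digital control bits into 16-bit waveform codes
#'
#' The four-channel waveform generator transmits digital control signals
#' (RF-unblank gate, ADC gate, phase reference) synchronously with the analog
#' waveforms by sacrificing one bit of the gradient channels: the amplitude is
#' quantized to 15 bits and shifted left by one, and the digital signal
#' occupies the least-significant bit of the 16-bit signed code. The same
#' packing carries the phase-reference square wave in receive channel 1.
#'
#' `pack_digital()` and [split_digital()] are exact inverses:
#' `split_digital(pack_digital(a, b))` returns `(a, b)` bit-for-bit.
#'
#' @param amplitude_codes integer vector of 15-bit signed amplitude codes,
#'   `|code| <= 2^14 - 1`.
#' @param bits integer/logical vector of 0/1 digital values, same length.
#' @return Integer vector of 16-bit signed codes.
#' @seealso [split_digital()], [mv_to_code15()]
#' @examples
#' codes <- pack_digital(c(-3L, 0L, 16383L), c(1L, 1L, 0L))
#' split_digital(codes)
#' @export
pack_digital <- function(amplitude_codes, bits) {
  if (length(amplitude_codes) != length(bits))
    stopf("amplitude and bit streams must have equal length")
  a <- as.numeric(amplitude_codes)
  b <- as.numeric(bits)
  if (any(!is.finite(a)) || any(abs(a - round(a)) > 0))
    stopf("amplitude codes must be integers")
  if (any(abs(a) > 2^14 - 1))
    stopf("amplitude code overflow: |code| must not exceed %d (15-bit signed)", 2^14 - 1)
  if (any(!(b %in% c(0, 1))))
    stopf("bits must be 0 or 1")
  as.integer(2 * a + b)
}

#' Split 16-bit codes into amplitude codes and digital bits
#'
#' Exact inverse of [pack_digital()].
#'
#' @param codes integer vector of packed 16-bit signed codes.
#' @return A list with integer elements `amplitude` and `bits`.
#' @export
split_digital <- function(codes) {
  b <- as.integer(codes %% 2L)
  list(amplitude = as.integer((as.numeric(codes) - b) / 2), bits = b)
}

# millivolt <-> code conversions ------------------------------------------
#
# 15-bit (packed gradient / receive) convention: one 15-bit step equals
# full_scale / 2^14 mV, so that clearing the digital bit and scaling the
# 16-bit code by full_scale / 2^15 recovers the analog value exactly.

mv_to_code15 <- function(mv, full_scale, what = "waveform") {
  code <- round_half_away(mv / full_scale * 2^14)
  bad <- abs(code) > 2^14 - 1
  if (any(bad))
    stopf("%s overflow: |%.6g mV| exceeds the 15-bit range (full scale %g mV); refusing to clip",
          what, max(abs(mv[bad])), full_scale)
  as.integer(code)
}

code15_to_mv <- function(code, full_scale) {
  as.numeric(code) * full_scale / 2^14
}

# Full 16-bit convention for the unpacked RF transmit channel.
mv_to_code16 <- function(mv, full_scale, what = "RF waveform") {
  code <- round_half_away(mv / full_scale * (2^15 - 1))
  bad <- abs(code) > 2^15 - 1
  if (any(bad))
    stopf("%s overflow: |%.6g mV| exceeds the 16-bit range (full scale %g mV); refusing to clip",
          what, max(abs(mv[bad])), full_scale)
  as.integer(code)
}

code16_to_mv <- function(code, full_scale) {
  as.numeric(code) * full_scale / (2^15 - 1)
}
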