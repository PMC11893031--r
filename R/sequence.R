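#' Pulse sequence definition
#'
#' In-memory model of a Pulseq-style pulse sequence: an ordered list of
#' blocks, each holding at most one RF event, up to three gradient events
#' (one per axis) and one ADC event, plus the global raster times. Gradient
#' amplitudes are in kHz/m, RF amplitudes in Hz of nutation frequency, all
#' times in seconds.
#'
#' @param blocks list of blocks created with [seq_block()].
#' @param definitions named list of raster times and free-form definitions;
#'   missing rasters are filled with the Pulseq v1.4 defaults.
#' @param metadata free-form named list (protocol parameters, encode table,
#'   ...), carried through file round trips via the JSON sidecar only.
#' @return An object of class `seq_def`.
#' @seealso [seq_block()], [rf_event()], [trap_event()], [adc_event()],
#'   [read_pulseq()], [write_pulseq()]
#' @export
seq_def <- function(blocks = list(), definitions = list(), metadata = list()) {
  defaults <- list(
    GradientRasterTime = 1e-5,
    RadiofrequencyRasterTime = 1e-6,
    AdcRasterTime = 1e-7,
    BlockDurationRaster = 1e-5
  )
  definitions <- modifyList(defaults, definitions)
  s <- structure(list(blocks = blocks, definitions = definitions,
                      metadata = metadata), class = "seq_def")
  validate_seq_def(s)
  s
}

#' Sequence block
#'
#' @param duration block duration in seconds (non-negative multiple of the
#'   block duration raster).
#' @param rf optional [rf_event()].
#' @param gx,gy,gz optional gradient events ([trap_event()] or [arb_event()]).
#' @param adc optional [adc_event()].
#' @return A list of class `seq_block`.
#' @export
seq_block <- function(duration, rf = NULL, gx = NULL, gy = NULL, gz = NULL,
                      adc = NULL) {
  structure(list(duration = duration, rf = rf,
                 grad = list(x = gx, y = gy, z = gz), adc = adc),
            class = "seq_block")
}

#' RF event
#'
#' A block (hard) pulse when `envelope` is `NULL`: constant complex amplitude
#' `amplitude` Hz over `duration`. Otherwise `envelope` holds complex samples
#' in Hz on the RF raster and `duration = length(envelope) * raster`.
#'
#' @param amplitude peak amplitude in Hz (nutation frequency, gamma*B1).
#' @param duration pulse duration in s (block pulse).
#' @param delay delay from block start in s.
#' @param freq_offset frequency offset in Hz.
#' @param phase_offset phase offset in rad.
#' @param envelope optional complex envelope samples (Hz) on `raster`.
#' @param raster envelope raster in s.
#' @return A list of class `rf_event`.
#' @export
rf_event <- function(amplitude, duration, delay = 0, freq_offset = 0,
                     phase_offset = 0, envelope = NULL, raster = 1e-6) {
  if (!is.null(envelope)) duration <- length(envelope) * raster
  structure(list(amplitude = amplitude, duration = duration, delay = delay,
                 freq_offset = freq_offset, phase_offset = phase_offset,
                 envelope = envelope, raster = raster), class = "rf_event")
}

#' Trapezoidal gradient event
#'
#' @param amplitude flat-top amplitude in kHz/m.
#' @param rise,flat,fall ramp-up, flat-top and ramp-down times in s.
#' @param delay delay from block start in s.
#' @return A list of class `trap_event`.
#' @export
trap_event <- function(amplitude, rise, flat, fall = rise, delay = 0) {
  structure(list(type = "trap", amplitude = amplitude, rise = rise,
                 flat = flat, fall = fall, delay = delay,
                 duration = delay + rise + flat + fall), class = "trap_event")
}

#' Arbitrary gradient event
#'
#' @param samples gradient samples in kHz/m on `raster`.
#' @param raster sample raster in s.
#' @param delay delay from block start in s.
#' @return A list of class `arb_event`.
#' @export
arb_event <- function(samples, raster = 1e-5, delay = 0) {
  structure(list(type = "arb", samples = samples, raster = raster,
                 delay = delay, duration = delay + length(samples) * raster),
            class = "arb_event")
}

#' ADC event
#'
#' @param num number of (decimated) readout samples.
#' @param dwell readout dwell time in s (inverse receive bandwidth); the gate
#'   spans `num * dwell` seconds of raw samples.
#' @param delay delay from block start in s.
#' @return A list of class `adc_event`.
#' @export
adc_event <- function(num, dwell, delay = 0) {
  structure(list(num = as.integer(num), dwell = dwell, delay = delay,
                 duration = delay + num * dwell), class = "adc_event")
}

grad_duration <- function(g) if (is.null(g)) 0 else g$duration

validate_seq_def <- function(s) {
  tol <- 1e-9
  for (i in seq_along(s$blocks)) {
    b <- s$blocks[[i]]
    if (!inherits(b, "seq_block")) stopf("block %d is not a seq_block", i)
    if (!is.finite(b$duration) || b$duration < -tol)
      stopf("block %d has invalid duration", i)
    ends <- c(
      if (!is.null(b$rf)) b$rf$delay + b$rf$duration,
      vapply(b$grad, grad_duration, numeric(1)),
      if (!is.null(b$adc)) b$adc$duration
    )
    if (length(ends) && max(ends) > b$duration + tol)
      stopf("block %d: event of duration %.6g s exceeds block duration %.6g s",
            i, max(ends), b$duration)
    for (g in b$grad)
      if (!is.null(g)) {
        amp <- if (g$type == "trap") g$amplitude else g$samples
        if (any(!is.finite(amp))) stopf("block %d: non-finite gradient amplitude", i)
      }
    if (!is.null(b$rf) && !is.finite(b$rf$amplitude))
      stopf("block %d: non-finite RF amplitude", i)
  }
  invisible(s)
}

#' Total duration of a sequence
#'
#' Exact sum of the block durations.
#'
#' @param seq a [seq_def()] object.
#' @return Duration in seconds.
#' @export
sequence_duration <- function(seq) {
  stopifnot(inherits(seq, "seq_def"))
  if (!length(seq$blocks)) return(0)
  sum(vapply(seq$blocks, function(b) b$duration, numeric(1)))
}

#' @export
print.seq_def <- function(x, ...) {
  n_rf <- sum(vapply(x$blocks, function(b) !is.null(b$rf), logical(1)))
  n_adc <- sum(vapply(x$blocks, function(b) !is.null(b$adc), logical(1)))
  cat(sprintf("<seq_def> %d blocks, %d RF events, %d ADC gates, duration %.6g s\n",
              length(x$blocks), n_rf, n_adc, sequence_duration(x)))
  invisible(x)
}

# Evaluate a gradient event (kHz/m) at times t (s) relative to block start.
eval_gradient <- function(g, t) {
  if (is.null(g)) return(rep(0, length(t)))
  if (g$type == "trap") {
    tt <- t - g$delay
    a <- g$amplitude
    up <- g$rise; fl <- g$flat; dn <- g$fall
    w <- numeric(length(t))
    if (up > 0) {
      in_up <- tt >= 0 & tt < up
      w[in_up] <- a * tt[in_up] / up
    }
    in_fl <- tt >= up & tt < up + fl
    w[in_fl] <- a
    if (dn > 0) {
      in_dn <- tt >= up + fl & tt < up + fl + dn
      w[in_dn] <- a * (1 - (tt[in_dn] - up - fl) / dn)
    }
    w
  } else {
    tt <- t - g$delay
    ts <- (seq_along(g$samples) - 1) * g$raster
    out <- approx(ts, g$samples, xout = tt, method = "linear",
                  yleft = 0, yright = 0, rule = 2)$y
    out[tt < 0 | tt > ts[length(ts)]] <- 0
    out
  }
}

# Complex RF envelope (Hz, rotating frame, including frequency/phase offsets)
# at times t relative to block start.
eval_rf_envelope <- function(rf, t) {
  if (is.null(rf)) return(rep(0 + 0i, length(t)))
  tt <- t - rf$delay
  inside <- tt >= 0 & tt < rf$duration
  env <- rep(0 + 0i, length(t))
  if (is.null(rf$envelope)) {
    env[inside] <- rf$amplitude
  } else {
    ts <- (seq_along(rf$envelope) - 1) * rf$raster
    re <- approx(ts, Re(rf$envelope), xout = tt[inside], rule = 2)$y
    im <- approx(ts, Im(rf$envelope), xout = tt[inside], rule = 2)$y
    env[inside] <- complex(real = re, imaginary = im)
  }
  ph <- rf$phase_offset + 2 * pi * rf$freq_offset * pmax(tt, 0)
  env * exp(1i * ph)
}
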