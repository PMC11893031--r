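#' Protocol parameters for the built-in sequences
#'
#' @param te echo spacing / echo time in s.
#' @param tr repetition time in s.
#' @param etl echo train length (refocused echoes per excitation).
#' @param fov field of view in m, length 3: (readout, PE1, PE2).
#' @param matrix matrix size, length 3: (readout, PE1, PE2). Use PE2 = 1 for
#'   two-dimensional protocols.
#' @param readout_bandwidth receive bandwidth in Hz; the ADC duration is
#'   `matrix[1] / readout_bandwidth`.
#' @param rf_duration block RF pulse duration in s.
#' @param dummy_shots excitations played before the imaging shots, with RF
#'   and gradients but no ADC, to drive the magnetization to steady state.
#' @param ordering phase-encode ordering, `"linear"` or `"inside-out"`.
#' @param gradient_correction_time extra readout-gradient flat time in s,
#'   inserted before the ADC gate opens (and mirrored after it closes) so the
#'   refocused echo stays centered despite system delays.
#' @param rise_time gradient ramp time in s.
#' @param pe_duration total duration of the phase-encode trapezoids in s.
#' @param flip_amplitude,refocus_amplitude RF amplitudes in Hz; default to
#'   the 90 and 180 degree amplitudes for `rf_duration`
#'   (`0.25 / rf_duration` and `0.5 / rf_duration`).
#' @return A list of class `protocol_params`.
#' @export
protocol_params <- function(te, tr, etl = 1L,
                            fov = c(0.24, 0.2, 0.21),
                            matrix = c(120L, 100L, 42L),
                            readout_bandwidth = 20e3,
                            rf_duration = 200e-6,
                            dummy_shots = 0L,
                            ordering = c("linear", "inside-out"),
                            gradient_correction_time = 0,
                            rise_time = 200e-6,
                            pe_duration = 1e-3,
                            flip_amplitude = NULL,
                            refocus_amplitude = NULL) {
  ordering <- match.arg(ordering)
  if (length(matrix) == 2L) matrix <- c(matrix, 1L)
  if (length(fov) == 2L) fov <- c(fov, fov[2])
  p <- structure(list(
    te = te, tr = tr, etl = as.integer(etl), fov = fov,
    matrix = as.integer(matrix), readout_bandwidth = readout_bandwidth,
    rf_duration = rf_duration, dummy_shots = as.integer(dummy_shots),
    ordering = ordering, gradient_correction_time = gradient_correction_time,
    rise_time = rise_time, pe_duration = pe_duration,
    flip_amplitude = flip_amplitude %||% (0.25 / rf_duration),
    refocus_amplitude = refocus_amplitude %||% (0.5 / rf_duration)
  ), class = "protocol_params")
  if (p$etl < 1L) stopf("etl must be >= 1")
  if (any(p$matrix < 1L)) stopf("matrix counts must be >= 1")
  if (p$te < p$rf_duration) stopf("te must be >= rf_duration")
  if (p$gradient_correction_time < 0) stopf("gradient_correction_time must be >= 0")
  p
}

# Symmetric phase-encode index values -N/2 .. N/2-1 (0 centered).
pe_indices <- function(n) seq.int(-floor(n / 2), length.out = n)

# Cartesian encode table in acquisition (chronological) order.
#
# The flattened (PE1 fastest, PE2 outermost) encode list is sorted — in plain
# lexicographic k-space order for "linear", by distance from the k-space
# centre for "inside-out" — and echo j of shot s acquires the
# ((j-1)*S + s)-th entry, S = ceil(Nenc/ETL). For linear ordering this
# banded assignment places the k-space centre line on echo ceiling(ETL/2);
# for inside-out on echo 1.
tse_encode_table <- function(n1, n2, etl, ordering) {
  nenc <- n1 * n2
  if (etl > nenc)
    stopf("echo train length %d exceeds the %d phase encodings", etl, nenc)
  pe1 <- rep(pe_indices(n1), times = n2)
  pe2 <- rep(pe_indices(n2), each = n1)
  canonical <- seq_len(nenc)             # lexicographic (pe2, pe1) position
  ord <- if (ordering == "inside-out") {
    r2 <- (pe1 / n1)^2 + (pe2 / max(n2, 1))^2
    order(r2, abs(pe2), pe2, abs(pe1), pe1)
  } else rev(canonical)                  # +k -> -k, centring echo ceil(ETL/2)
  s_count <- ceiling(nenc / etl)
  rows <- list()
  g <- 0L
  for (s in seq_len(s_count)) {
    for (j in seq_len(etl)) {
      idx <- (j - 1L) * s_count + s
      if (idx > nenc) next
      g <- g + 1L
      k <- ord[idx]
      rows[[g]] <- data.frame(gate = g, shot = s, echo = j,
                              enc = canonical[k], pe1 = pe1[k], pe2 = pe2[k])
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "shots") <- s_count
  tab
}

#' Effective echo time of a turbo spin echo acquisition
#'
#' The echo index at which the k-space centre line is acquired, multiplied by
#' the echo spacing. Linear ordering centres at echo `ceiling(etl / 2)`;
#' inside-out ordering acquires the centre on the first echo.
#'
#' @param ordering `"linear"` or `"inside-out"`.
#' @param etl echo train length.
#' @param echo_spacing echo spacing in s.
#' @return Effective TE in seconds.
#' @examples
#' compute_effective_te("linear", 22, 0.020)      # 0.22 s
#' compute_effective_te("inside-out", 5, 0.020)   # 0.02 s
#' @export
compute_effective_te <- function(ordering = c("linear", "inside-out"), etl,
                                 echo_spacing) {
  ordering <- match.arg(ordering)
  stopifnot(etl >= 1)
  centre_echo <- if (ordering == "linear") ceiling(etl / 2) else 1
  centre_echo * echo_spacing
}

#' Generate a Cartesian turbo spin echo sequence
#'
#' CPMG echo train: a 90 degree excitation block pulse, `etl` refocusing
#' pulses (phase-shifted by 90 degrees), a readout trapezoid per echo with
#' the ADC gate centred on the echo, and phase-encode blips/rewinders around
#' every readout. The readout flat time is extended by the gradient
#' correction time before the gate opens (mirrored after it closes so the
#' CPMG condition holds exactly). Dummy shots — full TR periods with RF and
#' gradients but no ADC — are prepended. The number of imaging shots is
#' `ceiling(encodings / etl)` and the total duration is
#' `(shots + dummy_shots) * tr`.
#'
#' @param params a [protocol_params()] object.
#' @param dims 2 or 3 encoded dimensions.
#' @return A [seq_def()] whose `metadata` carries the encode table
#'   (chronological gate order with k-space positions), the shot count and
#'   the effective TE.
#' @export
make_tse <- function(params, dims = 2) {
  stopifnot(inherits(params, "protocol_params"), dims %in% c(2, 3))
  p <- params
  n_ro <- p$matrix[1]
  n1 <- p$matrix[2]
  n2 <- if (dims == 3) p$matrix[3] else 1L
  bw <- p$readout_bandwidth
  adc_dur <- n_ro / bw
  dwell <- 1 / bw
  rise <- p$rise_time
  gc <- p$gradient_correction_time
  g_ro <- bw / (1000 * p$fov[1])                 # kHz/m
  ro_flat <- adc_dur + 2 * gc

  tab <- tse_encode_table(n1, n2, p$etl, p$ordering)
  shots <- attr(tab, "shots")

  gap1 <- p$te / 2 - p$rf_duration
  gap2 <- p$te / 2 - p$rf_duration / 2 - (rise + gc + adc_dur / 2)
  fill <- p$tr - p$te / 2 - p$etl * p$te
  if (gap1 <= 0 || gap2 < p$pe_duration || fill < 0)
    stopf("TSE timing infeasible: te/tr too short for rf_duration=%g, rise=%g, adc=%g, pe=%g",
          p$rf_duration, rise, adc_dur, p$pe_duration)

  pre_flat <- min(p$pe_duration, gap1 - 2 * rise)
  if (pre_flat <= 0) stopf("no room for the readout prephaser within te/2")
  a_pre_area <- g_ro * (rise / 2 + gc + adc_dur / 2)
  a_pre <- a_pre_area / (pre_flat + rise)

  pe_flat <- p$pe_duration - 2 * rise
  if (pe_flat <= 0) stopf("pe_duration must exceed twice the rise time")
  pe_area <- function(m, fov) m / (1000 * fov)   # kHz/m * s
  pe_amp <- function(m, fov) pe_area(m, fov) / (pe_flat + rise)

  ex_rf <- rf_event(p$flip_amplitude, p$rf_duration)
  ref_rf <- rf_event(p$refocus_amplitude, p$rf_duration, phase_offset = pi / 2)
  ro_grad <- trap_event(g_ro, rise, ro_flat, rise)
  adc <- adc_event(n_ro, dwell, delay = rise + gc)
  pre_grad <- trap_event(a_pre, rise, pre_flat, rise)

  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b

  one_shot <- function(shot_tab, imaging) {
    add(seq_block(p$rf_duration, rf = ex_rf))
    add(seq_block(gap1, gx = pre_grad))
    for (j in seq_len(p$etl)) {
      row <- if (imaging) shot_tab[shot_tab$echo == j, , drop = FALSE] else NULL
      acquire <- imaging && nrow(row) == 1L
      m1 <- if (acquire) row$pe1 else 0
      m2 <- if (acquire) row$pe2 else 0
      add(seq_block(p$rf_duration, rf = ref_rf))
      enc_gy <- if (m1 != 0) trap_event(pe_amp(m1, p$fov[2]), rise, pe_flat, rise)
      enc_gz <- if (dims == 3 && m2 != 0) trap_event(pe_amp(m2, p$fov[3]), rise, pe_flat, rise)
      add(seq_block(gap2, gy = enc_gy, gz = enc_gz))
      add(seq_block(2 * rise + ro_flat, gx = ro_grad,
                    adc = if (acquire) adc))
      rew_gy <- if (m1 != 0) trap_event(-pe_amp(m1, p$fov[2]), rise, pe_flat, rise)
      rew_gz <- if (dims == 3 && m2 != 0) trap_event(-pe_amp(m2, p$fov[3]), rise, pe_flat, rise)
      add(seq_block(gap2, gy = rew_gy, gz = rew_gz))
    }
    if (fill > 0) add(seq_block(fill))
  }

  for (d in seq_len(p$dummy_shots)) one_shot(NULL, imaging = FALSE)
  for (s in seq_len(shots)) one_shot(tab[tab$shot == s, , drop = FALSE], TRUE)

  seq_def(blocks = blocks, metadata = list(
    protocol = sprintf("tse%dd", dims), dims = dims, params = p,
    encode_table = tab, shots = shots, n_encodings = n1 * n2,
    effective_te = compute_effective_te(p$ordering, p$etl, p$te),
    adc_duration = adc_dur, readout_bandwidth = bw
  ))
}

#' Generate a free induction decay (FID) sequence
#'
#' One RF block pulse, then a single ADC gate after a configurable dead time.
#' The basis of the Larmor-frequency, flip-angle and shim calibrations.
#'
#' @param rf_duration RF block pulse duration in s.
#' @param adc_duration ADC gate duration in s.
#' @param readout_bandwidth receive bandwidth in Hz (sets the ADC dwell).
#' @param dead_time delay between the end of the pulse and the gate, s.
#' @param lead_delay delay before the pulse, s.
#' @param flip_amplitude RF amplitude in Hz; defaults to the 90 degree
#'   amplitude `0.25 / rf_duration`.
#' @return A [seq_def()] with one RF block and one ADC block.
#' @export
make_fid <- function(rf_duration = 200e-6, adc_duration = 6e-3,
                     readout_bandwidth = 20e3, dead_time = 1e-3,
                     lead_delay = 0, flip_amplitude = NULL) {
  amp <- flip_amplitude %||% (0.25 / rf_duration)
  num <- round(adc_duration * readout_bandwidth)
  blocks <- list(
    seq_block(lead_delay + rf_duration,
              rf = rf_event(amp, rf_duration, delay = lead_delay)),
    seq_block(dead_time + num / readout_bandwidth,
              adc = adc_event(num, 1 / readout_bandwidth, delay = dead_time))
  )
  seq_def(blocks = blocks, metadata = list(
    protocol = "fid", rf_duration = rf_duration, flip_amplitude = amp,
    adc_duration = num / readout_bandwidth,
    readout_bandwidth = readout_bandwidth,
    dead_time = dead_time, lead_delay = lead_delay))
}

#' Generate the hardware monitoring sequence
#'
#' A single block holding a 400 microsecond RF block pulse followed by three
#' consecutive 80 kHz/m trapezoidal gradients of 2 ms on the x, y and z
#' axes with 1 ms spacings, a 1 ms leading delay and a 1 ms trailing dead
#' time. One ADC gate covers the whole active section, opening at the end of
#' the leading delay and closing at the beginning of the dead time. Used to
#' monitor RF performance and gradient fidelity (amplifier gain, timing
#' delay) on auxiliary receive channels.
#'
#' @param rf_duration RF pulse duration in s.
#' @param grad_amplitude trapezoid amplitude in kHz/m.
#' @param grad_duration total trapezoid duration in s.
#' @param spacing gap after each gradient in s.
#' @param lead_delay,dead_time leading delay / trailing dead time in s.
#' @param readout_bandwidth receive bandwidth in Hz (sets the ADC dwell).
#' @param grad_rise trapezoid ramp time in s.
#' @return A [seq_def()] with a single block and exactly one ADC gate.
#' @export
make_monitoring <- function(rf_duration = 400e-6, grad_amplitude = 80,
                            grad_duration = 2e-3, spacing = 1e-3,
                            lead_delay = 1e-3, dead_time = 1e-3,
                            readout_bandwidth = 20e3, grad_rise = 200e-6) {
  active <- rf_duration + 3 * (grad_duration + spacing)
  total <- lead_delay + active + dead_time
  flat <- grad_duration - 2 * grad_rise
  if (flat <= 0) stopf("grad_duration must exceed twice the rise time")
  g_delay <- function(k) lead_delay + rf_duration +
    (k - 1) * (grad_duration + spacing)
  num <- round(active * readout_bandwidth)
  blk <- seq_block(
    total,
    rf = rf_event(0.25 / rf_duration, rf_duration, delay = lead_delay),
    gx = trap_event(grad_amplitude, grad_rise, flat, grad_rise, delay = g_delay(1)),
    gy = trap_event(grad_amplitude, grad_rise, flat, grad_rise, delay = g_delay(2)),
    gz = trap_event(grad_amplitude, grad_rise, flat, grad_rise, delay = g_delay(3)),
    adc = adc_event(num, 1 / readout_bandwidth, delay = lead_delay)
  )
  seq_def(blocks = list(blk), metadata = list(
    protocol = "monitoring", adc_span = num / readout_bandwidth,
    grad_amplitude = grad_amplitude))
}
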