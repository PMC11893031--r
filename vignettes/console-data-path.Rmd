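---
title: "The virtual console data path: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The virtual console data path: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrconsole)
```

`mrconsole` models the digital data path of a multi-channel low-field MRI
console end to end, replacing the arbitrary-waveform generator and the
digitizer with a virtual scanner. This vignette documents the models, the
conventions chosen where the hardware leaves them open, and the numerical
decisions a user relying on the simulated chain should know about.

## Sequence compilation

A Pulseq v1.4 sequence is a list of blocks, each holding at most one RF
event, one gradient event per axis, and one ADC event. `unroll_sequence()`
samples every event onto the shared converter raster `1 / raw_sample_rate`:
trapezoids piecewise-linearly, arbitrary gradients by linear interpolation.
Scalings live in `acq_params()`:

* `gradient_scaling` (mV per kHz/m, per axis) is the composite of gradient
  coil efficiency, amplifier gain, gyromagnetic ratio and FOV scaling. Its
  numeric value is hardware-specific; the default of 50 mV/(kHz/m) places
  typical imaging gradients comfortably inside the +/-12 V output range.
* `gradient_offset` (mV, per axis) is a static shim voltage added to the
  whole waveform — it produces a real gradient field, which is exactly why
  offset calibration can shim out a linear B0 inhomogeneity.
* `b1_scaling` (mV per Hz of nutation) converts the RF envelope; the
  envelope is then modulated with the Larmor frequency.

**Carrier phase convention.** The carrier phase at absolute time `t` is
`2 pi f0 t` with `t = 0` at sequence start, continuous across blocks. This
makes demodulation with a reconstructed reference coherent across gates; any
per-pulse phase offset (e.g. the 90-degree shift of refocusing pulses) is
added on top.

**Digital bit packing.** Three digital control signals travel with the
analog waveforms in the "16th bit" of the gradient channels. We interpret
that bit as the least-significant bit of the 16-bit signed code: the
amplitude is quantized to 15 bits (`|code| <= 2^14 - 1`, one step =
`full_scale / 2^14`) and shifted left by one, so `pack`/`split` are exact
inverses and sign arithmetic is untouched. The assignment — RF-unblank on
Gx, ADC gate on Gy, phase reference on Gz, and the phase reference again in
receive channel 1 — is configurable (`bit_map`), since the physical wiring
is a site choice. RF-unblank opens 10 microseconds before each pulse by
default (`rf_lead`), mirroring amplifier gating practice.

**Overflow policy.** Any amplitude outside the representable range is a
hard error. Silent clipping would corrupt flip angles and k-space scaling
in ways that are very hard to notice downstream.

Quantization rounds half away from zero, symmetric in sign.

## Protocol generation

`make_tse()` builds a CPMG turbo spin echo: a 90-degree block pulse, `etl`
refocusing pulses phase-shifted by 90 degrees, one readout per echo with
the ADC gate centred on the echo, and phase-encode blips/rewinders around
every readout. Timing is fully determined by `te` (echo spacing), the RF
duration, ramp times and the ADC duration; each shot is padded to exactly
`tr`, so the sequence duration is `(shots + dummy_shots) * tr` with
`shots = ceiling(encodings / etl)`.

**Gradient correction time.** Eddy currents delay the refocused echo
relative to the gate on real systems; the protocol therefore extends the
readout flat time before the ADC gate opens. We mirror the same pad after
the gate closes, which keeps the CPMG refocusing condition exact for any
correction value — the one-sided pad alone would accumulate `g * t_corr` of
unbalanced area per echo. The correction value itself is measured with
`estimate_gradient_delay()` from monitored gradient waveforms.

**Phase-encode ordering.** The flattened (PE1 fastest, PE2 outermost)
encode list is sorted and assigned band-wise: echo `j` of shot `s` acquires
the `((j - 1) S + s)`-th sorted line. For linear ordering the sort runs
from +k to -k, which places the k-space centre line on echo
`ceiling(etl / 2)` for every matrix size — consistent with
`compute_effective_te()`, which reproduces the 220 ms effective TE of a
22-echo train at 20 ms spacing. Inside-out ordering sorts by distance from
the centre, acquiring it on echo 1. The echo train runs straight over the
flattened multi-slab list, so partial trains occur only at the outer edge
of k-space.

Crusher and spoiler gradients are not generated; refocusing pulses are
ideal block pulses. Dummy shots (full TR periods without ADC) are the
mechanism provided for reaching a steady state.

## The virtual scanner

`simulate_acquisition()` evolves an isochromat ensemble through the
compiled waveforms:

* **Hard-pulse model.** During RF activity the ensemble is rotated in
  chunks on a 10 microsecond internal raster, with the off-resonance and
  gradient precession split symmetrically around each rotation
  (second-order accurate). Between pulses the transverse magnetization is
  propagated in closed form from the cumulative gradient integrals, so ADC
  samples are exact at the raw raster — there is no accumulation of
  per-step integration error across a TR.
* **Gradient read-back.** The spins see `mV / gradient_scaling`, with the
  mV decoded from the packed 16-bit codes — including the static shim
  offset, and including quantization. The RF envelope is carried alongside
  the frames in mV and divided by a virtual transmit efficiency
  (`tx_efficiency`, default 1 mV/Hz), which closes the B1-calibration loop:
  doubling `b1_scaling` halves the commanded amplitude that produces a
  90-degree flip.
* **Relaxation.** T2 decay and T1 recovery. T1 is essential, not a luxury:
  with transverse-only relaxation the longitudinal magnetization never
  recovers after the first excitation, every later shot re-excites only
  leftover coherences, and multi-shot k-space becomes inconsistent in a way
  that depends on the acquisition order. Low-field defaults are
  `t2 = 0.1 s`, `t1 = 0.3 s`. T2* inhomogeneity is represented only through
  explicit per-spin `off_resonance` values.
* **EMI.** Each `make_emi()` source is a complex analytic waveform (tone,
  or band-limited noise) convolved with a per-channel complex coupling
  kernel drawn reproducibly from the source seed. The MR channel receives
  the source through its own kernel too — interference leaks into the
  primary coil just as it reaches the sensors. Sources superpose linearly
  before quantization. No quantitative coupling values are published for
  such setups; kernel scales are free scenario parameters.
* **Buffer bound.** Gated samples, summed over channels, must fit the
  512 MS digitizer buffer (`rx_buffer_capacity`): 25.6 s of gate at
  20 MS/s on one channel, 3.2 s on eight. The bound is checked before any
  memory is committed.

## Receive chain

Demodulation multiplies by `2 exp(-i (2 pi f0 tau + phi))`, where `phi` is
the carrier phase recovered from the packed phase-reference bit: the
+/-1-mapped bit stream is projected onto `exp(i 2 pi f0 tau)` (the
least-squares amplitude of its fundamental) and its argument taken. Square-
wave harmonics are orthogonal to the fundamental over the gate unless the
carrier is a small rational fraction of the raster rate; the shipped
configurations avoid `f0 = fs/4` for that reason. With the reference absent
the chain falls back to the absolute-time phase `2 pi f0 t_start`.

The decimation filter is a windowed-sinc (Hamming) FIR with cutoff at half
the receive bandwidth, length `8 R + 1` capped at 4001 taps, normalized to
unit DC gain, applied by FFT convolution; output samples are taken at the
filter's group delay plus multiples of `R`, so a symmetric echo at the gate
centre lands on the central readout sample (`n/2 + 1`, the same pixel the
centred FFT calls the origin). The first and last `~gd / R` readout samples
of every gate carry the filter's warm-up transient — at the hardware
operating point (`R = 1000`, 4001 taps) that is two samples per edge.
A pure carrier of amplitude A mV demodulates to complex magnitude A; the
filter never amplifies (max gain < 1.01).

## EDITER interference removal

For each k-space line, `primary ~ sum_d conv(detector_d, kernel_d)` is
solved jointly over all detectors by SVD least squares (7 complex taps per
detector by default). Lines whose kernels have normalized inner product of
at least `group_correlation_threshold` (default 0.5) with the running group
mean are merged greedily in chronological order and re-solved jointly —
stacked per line, so no convolution bleeds across line boundaries.

The published description of such setups fixes no solver settings, so two
numerical choices are ours:

* **Rank handling.** Exactly dependent detector columns are an error
  advising regularization (all-zero detectors short-circuit to zero
  kernels). The ridge `solver_regularization` is *relative* to the squared
  largest singular value, making it invariant to the interference scale.
* **Narrowband regime.** A pure tone makes all tap shifts nearly collinear;
  unregularized per-line solves then overfit the MR signal with wild
  kernels and grouping degenerates. A small relative ridge (`1e-4` in the
  shipped scenario, on a broad plateau between `1e-5` and `3e-4`)
  stabilizes the kernels, grouping consolidates the scan, and the joint
  solves remove over 20 dB of image-domain artifact power in the
  tone-interference phantom scenario.

On interference-free input with all-zero detector channels the output is
bit-identical to the input.

## Calibration conventions

The calibrations operate on any backend exposing `acquire(seq, params)`;
`virtual_backend()` provides the simulated one. Objectives: spectral peak
of the FID (Larmor), FID magnitude integral (flip angle and shims). Choices
worth noting:

* The Larmor spectrum is zero-padded eightfold before the parabolic
  sub-bin refinement; convergence requires the peak to exceed three times
  the spectral noise floor (95th percentile of the magnitude bins).
* The flip-angle objective `|sin(flip)|` is periodic; the sweep takes its
  *first* peak (within 95 % of the global maximum), not a later 270-degree
  maximum, and flags edge optima as non-converged.
* Shims are searched coordinate-wise (x, y, z) with one quadratic
  refinement per axis; the FID-integral objective is sinc-like in the
  residual gradient, so grids should straddle the optimum by a few steps.
* `estimate_gradient_delay()` cross-correlates without demeaning (gradient
  monitor waveforms are transient on a zero baseline; demeaning biases a
  flat-topped correlation) and refines the peak parabolically to below
  0.1 sample for band-limited waveforms.
* `b0_shift_to_frequency()` multiplies by 42.577478518 MHz/T; 2.63 uT
  maps to 112.0 Hz.

## Desk-scale study conditions

The test suite and scenario fixtures run the identical code path at a
reduced operating point chosen once: a 100 kS/s raster with a 21.3 kHz
carrier (deliberately incommensurate with the raster), 5 kHz receive
bandwidth (decimation 20), 32 x 32 imaging matrices over a 12 cm FOV, a
7 cm sphere phantom of ~550 isochromats, an 8-echo train at 16 ms spacing
with TR 0.5 s and two dummy shots. Every rate-dependent identity
(decimation factor, buffer arithmetic, 50 ns spacing, 120-sample readouts)
is additionally asserted at the hardware operating point itself, where the
computation is cheap. Calibration recovery is verified on 20 randomized
(off-resonance, B1 scaling, shim gradient) configurations.

## What the simulation does and does not show

The virtual scanner validates the *data path*: scaling, packing, gating,
timing, coherence, sorting, interference removal, calibration logic. It
does not emulate B0 maps of real magnets (>100 ppm inhomogeneity),
coil sensitivity profiles, eddy currents (the gradient correction time is
exercised arithmetically, not physically), temperature drift dynamics,
amplifier nonlinearity, or dither-based resolution enhancement of the
packed gradient channels. Passing tests therefore demonstrate correctness
of the chain, not image quality on any particular magnet. In-vivo
quantities published for comparable hardware (SNR ratios against commercial
consoles, whole-brain protocol durations under partial k-space coverage)
are out of scope for the desk-scale phantom conditions.
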