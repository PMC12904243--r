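---
title: "Temporal-masking pulse sparsification for cochlear implants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-masking pulse sparsification for cochlear implants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipscoder)
```

## The problem

A cochlear implant (CI) converts sound into a train of biphasic current
pulses on an intracochlear electrode array. Conventional coding strategies —
continuous interleaved sampling (CIS) and its N-of-M descendant ACE — fire
channels at a fixed per-channel rate, so a large share of the delivered
pulses fall in envelope troughs or immediately after much stronger pulses on
the same electrode, where the auditory system is unlikely to register them.
Every such pulse still costs charge, and the radio-frequency (RF) link that
powers the implant is the dominant battery drain.

The temporal integrator processing strategy (TIPS) implemented here is a
post-processor on the encoded pulse pattern: it predicts, pulse by pulse,
whether removing the pulse would produce a detectable change in the output
of a temporal-masking model, and deletes the pulses that would not be
missed. The package implements the whole chain needed to study this
behaviour on synthetic signals: the acoustic front end, the CIS/ACE
encoders, the masking-window decision device with criterion calibration, a
device-level power-savings model, stimulus generators, and a simulator of
the adaptive speech-reception-threshold (SRT) protocol used to evaluate such
strategies with listeners.

## The coding chain

**Calibration and pre-emphasis.** Signals are first normalized to a
root-mean-square level of −20 dB FS (`normalize_rms()`). A first-order
Chebyshev type II high-pass (`pre_emphasize()`) then mimics the front-end
pre-emphasis of clinical processors. At order one the type II prototype has
no finite zero, so the filter reduces to a single-pole high-pass whose
attenuation at the stopband edge equals the design value exactly; the
default design places the edge at 4 kHz with 3 dB of attenuation. The
design-terminology pairing of a 4 kHz "corner" with an 8 kHz "edge" does not
uniquely determine a first-order section, so the edge frequency is a plain
argument (`stopband_hz`); an 8 kHz edge is only realizable above a 16 kHz
sample rate. No automatic gain control or noise reduction is applied
anywhere.

**Filterbank envelopes.** `analyze_envelopes()` resamples to 16 kHz, cuts
128-sample frames at the per-channel stimulation rate (frame starts at
`k/rate`, end of signal zero-padded), applies a periodic Hann window and an
FFT, and combines the bins of each band by root-sum-of-squares of bin
magnitudes. Power combining is deliberate: under the Hann bin pattern
(−0.25, +0.5, −0.25) a *coherent* complex sum cancels a bin-centered tone
almost entirely, whereas the power sum is insensitive to the tone's phase
and position within the band. The 22-band allocation table (per-band bin
counts 1,1,…,7,8 over FFT bins 2–63, roughly 190 Hz – 8 kHz) is the
conventional one for this device family and ships as a default
(`default_band_allocation()`); maps with fewer channels merge the 22 bands
into contiguous groups spanning the full range. Envelope values more than
200 dB below their frame maximum are floored to zero — they are FFT
round-off, and letting them through would create phantom "stimulating"
pulses of magnitude ~1e−13 after compression.

**Compression.** `compress_lgf()` applies the loudness growth function
`v = log(1 + ρ(p−b)/(s−b)) / log(1+ρ)` with base `b = 0` and saturation
`s = 0.39` (the published map settings) clipped to [0, 1]. The steepness
ρ is not published for these maps; the conventional coder default 416.2 is
used and is configurable. Magnitudes throughout the package are these
post-compression values in [0, 1]; `to_cu()` maps them linearly onto each
electrode's T–C dynamic range in clinical current units.

**Encoders and timing.** `encode_cis()` delivers one pulse per channel per
cycle; `encode_ace()` first selects the `n_maxima` largest-envelope channels
(`select_maxima()`, ties to the lower electrode number). Within a cycle,
channels fire apex-to-base by default at consecutive slots of
`2·phase + inter-phase gap + overhead` µs; the default 7 µs scheduling
overhead is chosen so that a 900 pps map with 62 µs phases and an 8 µs gap
admits exactly 7 interleaved channels while 50 µs phases admit at least 8,
matching the clinical-device behaviour that motivates
`max_channels_per_cycle()`. Frames whose compressed envelope is zero still
emit timing slots flagged non-stimulating (magnitude 0), so that removal
percentages always refer to pulses that actually deliver charge; the
`emit_zero_slots = FALSE` variant drops them instead.

## The masking model and decision device

The temporal-integrator window

$$W(t) = \begin{cases}(1-r)\,e^{t/\tau_{b1}} + r\,e^{t/\tau_{b2}} & t < 0\\
e^{-t/\tau_a} & t \ge 0\end{cases}$$

with $\tau_{b1} = 4.6$ ms, $\tau_{b2} = 16.6$ ms, $\tau_a = 3.5$ ms,
$r = 0.17$, describes how much a pulse at time offset $t$ from a probe
contributes to the percept at the probe: the double exponential on the
$t<0$ side is forward masking (maskers that precede), the single exponential
on the $t \ge 0$ side backward masking. The window is truncated at ±75 ms —
the backward side is exactly the look-ahead a real-time implementation would
have to buffer.

The sliding integrator output at time $t$ over a single channel's pulses is
$O(t) = \sum_p x_p^2\, W(t_p - t)$ (intensity domain by default; a
magnitude-domain variant is selectable). Note the orientation: a pulse
*earlier* than $t$ enters through the forward-masking branch. For a
candidate pulse the decision statistic is

$$S_i = \max_{|t - t_i| \le 75\,\mathrm{ms}}\; 10\log_{10}
\frac{O_\mathrm{with}(t)}{O_\mathrm{without}(t)},$$

the largest level difference that removing the pulse would create anywhere
inside the window. Three numerical conventions matter and are all explicit
in `decision_config()`:

* **Log convention and domain.** A literal log of an amplitude difference in
  [0, 1] could never exceed a positive dB criterion, so the statistic is a
  *level difference* between the with- and without-pulse outputs. The
  default is 10·log10 on intensities; because the statistic is a ratio, it
  is invariant to rescaling a channel's magnitudes — the tested scaling
  invariance — which is why criterion *calibration*, not the absolute dB
  convention, carries the scientific content.
* **Floor.** Where $O_\mathrm{without} \le$ `floor_eps` (10⁻¹²) the
  reference pattern carries no masking energy; such grid points are excluded
  from the maximum. If the whole window is floored the pulse is isolated:
  its statistic is reported as +∞ and it is never removed, at any criterion.
* **Scan mode.** `batch` (default) evaluates every pulse against the
  *original* pattern, making decisions order-independent and
  permutation-invariant; `sequential` scans in time order against the
  already-pruned pattern. Both are provided because the distinction cannot
  be settled from the published description; all removal-fraction behaviour
  in this package is reported per mode.

A pulse is removed when its statistic does not exceed the criterion
(boundary included). Channels are processed independently; cross-channel
masking is out of scope by design.

`calibrate_criterion()` inverts the criterion → removal-fraction map. In
batch mode the statistics are computed once and the criterion is their
empirical quantile (the k-th order statistic, k = round(target·n)), so the
achieved fraction is exact to 1/n; in sequential mode a bisection runs until
the achieved fraction is within 0.005 of the target or 40 iterations. The
published criteria (1.3 dB ↔ 50% on CIS-coded speech) are material-specific:
on this package's synthetic speech-shaped noise the 50% criterion lands
nearer 0.5 dB, which is exactly why calibration is exposed as the primary
interface and fixed criteria as the secondary one.

**Implementation note.** The batch path snaps each channel's pulse times to
its stimulation-period grid (warning above 0.1% of a period of error),
computes the integrator output by one FFT convolution per channel, and
evaluates all per-pulse windows as matrix slices — about 1 s for 10 s of
8-channel 900 pps audio. `decision_statistic()` and sequential mode instead
use exact pulse times on a target-centered grid; on-grid the two paths
agree to rounding, and both are tested against a loop-written brute-force
oracle.

## Power model

Charge steps are clinical current units: one CU multiplies current by
`100^(1/255)`, i.e. 40/255 dB = 0.156863 dB (usually quoted rounded to
0.157 dB). The exact step is the default because published charge
percentages are integer-CU quantized: +14 CU is +28.77% under the exact
step but +28.80% under the rounded one.

`net_power_saving()` models the device: a `coil_fraction` (default 90%) of
total power feeds the RF coil and scales linearly with stimulation, the rest
is fixed electronics overhead. Keeping a fraction $f$ of pulses at a
fractional per-pulse charge change $\Delta q$ scales coil power by
$f(1+\Delta q)$, so the net saving is

$$P_\mathrm{saved} = c\,\bigl(1 - f(1 + \Delta q)\bigr) \times 100\%, \qquad c = 0.9.$$

Removing one third of pulses means $f = 2/3$ exactly (not 0.67): that choice
is validated against every per-participant cell of the published table
(`table2_report()`, ±0.02 percentage points, two cells carrying last-digit
rounding slack). One caveat is documented rather than hidden: the published
TIPS33 *column average* (21.78%) is not the mean of the published
per-participant cells (22.11) nor the value this model produces from the
printed charge column (22.12); it is reproducible only with a retained
fraction of 0.67 applied to the column-average charge. The package reports
the model's own averages; the other two column averages (42.28%, 33.55%)
agree with print exactly because the model is linear in charge at fixed
retained fraction. Absolute nanocoulomb values are not modelled — they
depend on unpublished per-participant C-levels — so the model works in
relative charge throughout. Report rounding is half-up to two decimals with
raw values retained.

## Synthetic stimuli

All generators are pure functions of their seed (RNG state is saved and
restored), so every experiment in the test suite is bit-reproducible.

* `gen_ssn()` shapes Gaussian noise in the FFT domain to a third-octave
  reference spectrum. The packaged default spectrum
  (`speech_spectrum_default()`) is a *synthetic stand-in* for a long-term
  average speech spectrum — the spectrum of the actual matrix-test sentences
  is not published — so tests assert band-shape agreement of the generator
  with its own reference (within 1 dB for ≥5 s, bands fully below Nyquist),
  never equivalence to any recorded material.
* `gen_speech_token()` builds unintelligible speech-like tokens: 3–5 Hz
  syllables, each a harmonic complex (F0 100–250 Hz, formant-like peaks) or
  a high-pass noise burst, with pauses. `gen_babble()` sums `n_talkers`
  such streams (default 20) at random onsets; the tests check the
  qualitative statistics that define babble (modulation depth and kurtosis
  fall as talkers are added), not phonetic realism.
* `mix_at_snr()` leaves the speech untouched and scales a randomly drawn
  noise segment — the noise-level-varied design of adaptive SRT testing.

Passing tests on these materials demonstrate the chain's *mechanics*
(conservation, monotonicity, calibration, timing) — not speech
intelligibility outcomes, which depend on real speech, real noise and real
listeners and are explicitly outside what desk-scale simulation can claim.

## SRT simulation

`measure_srt()` reproduces the measurement *protocol*: adaptive tracks
start at 0 dB SNR, presented SNRs are clamped to [−15, +30] dB, each track
presents 20 sentences of 5 scored words, the SRT is the mean presented SNR
at the last 8 reversals, and a third track is triggered when the first two
SRTs differ by more than 4 dB or a track under-reverses. The listener is a
logistic psychometric model (`listener_model()`; 50% at `srt50`, slope in
proportion/dB, optional lapse), and word scores are binomial draws.

The SNR update rule is a documented stand-in, since the constants of the
staircase used with human listeners are not available here: the update is
word-score proportional, `ΔSNR = −step · (p − 0.5)/0.5`, with the step
halving after each of the first 4 reversals from 5 dB down to a 1 dB
minimum, and a reversal defined as a sign change between consecutive
nonzero updates. The suite checks the properties that matter for using the
simulator as a test harness: bit-reproducibility, bound enforcement,
convergence for a near-step listener, retest-rule firing exactly on its
condition, mean bias below 1 dB over 200 seeded runs at slope 0.15/dB, and
RMSE shrinking when tracks are lengthened.

## Problem sizes, defaults and limitations

The test suite and the reproduction script run the pruning chain on 10 s of
speech-shaped noise through an 8-channel 900 pps CIS map (72 000
stimulating pulses), calibrate at that size, and use 200 seeded runs for the
SRT bias estimate; these sizes give calibration resolution of ~1.4·10⁻⁵ in
removal fraction and a standard error on the SRT bias estimate well below
the 1 dB acceptance band.

Known limitations, all deliberate: no cross-channel masking (per-channel
processing is part of the model's definition here); no real-time/causal
variant (the backward window needs 75 ms of look-ahead); stimulation mode
labels (e.g. MP1+2) are metadata, not an electrical model; babble and
speech tokens are statistical proxies; and no claim is made that the
published criterion↔fraction pairs transfer to other material — calibrate
on the pattern at hand instead.
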