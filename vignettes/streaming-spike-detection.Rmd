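---
title: "Streaming fixed-point spike detection: model, datapath and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming fixed-point spike detection: model, datapath and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeflow)
```

## What this package models

spikeflow is a desk-scale emulation of a hardware datapath for
real-time extracellular spike detection: a controller receives a
serially multiplexed stream of 16-bit samples from up to 8 headstages
of 16 channels each (128 channels total), and for every sampling
period — one *frame*, announced by a synchronization word — it
highpass-filters each channel, applies a three-sample negative-peak
threshold rule with a per-channel refractory counter, and re-encodes
the filtered samples plus spike flags in place of the raw data. A
single shared filter/detector datapath serves all channels in series,
with per-channel state held in a 128-slot store; this is what keeps
the hardware cost independent of the channel count, and it is the
property the package's equivalence tests target.

The package's claim is deliberately narrow and exactly testable: the
streaming engine, fed frames in real-time order, produces *bit-for-bit*
the same filtered samples and the same spike times as an offline batch
run of the identical arithmetic on each channel's stored trace. Both
arms are folds of the same per-sample automaton, so any discrepancy
indicates a defect in the state multiplexing, the codec, or the
arithmetic — never an acceptable approximation error.

## The highpass filter

Spikes ride on a baseline contaminated by low-frequency field
potentials and drift, so each channel is filtered by a 2nd-order
highpass Butterworth section with cutoff $f_c = 300$ Hz, realized in
Direct-Form-II (two delay states per channel). The design is the
closed-form bilinear transform with prewarp $K = \tan(\pi f_c / f_s)$:

$$
b = \frac{(1, -2, 1)}{1 + \sqrt2 K + K^2}, \qquad
a_1 = \frac{2(K^2 - 1)}{1 + \sqrt2 K + K^2}, \qquad
a_2 = \frac{1 - \sqrt2 K + K^2}{1 + \sqrt2 K + K^2}.
$$

The feedforward taps sum to zero (exact DC rejection) and the response
at $f_c$ is $1/\sqrt2$.

```{r}
design_highpass_butterworth(20000, 300)[c("b0", "b1", "b2", "a1", "a2")]
```

### Fixed-point realization

The production path is integer-only, mirroring an FPGA implementation
with 18-bit multipliers:

* Coefficients are quantized to signed Q2.16 (`round(c * 2^16)`, half
  away from zero). `qb1` is then forced to `-(qb0 + qb2)`, so the
  quantized filter retains an *exact* DC zero — otherwise rounding can
  leak a permanent offset through the feedforward taps.
* States are 32-bit integers at `input << 16` scale. One step computes
  `w = sat32((x << 16) - ((qa1*w1 + qa2*w2) >> 16))`, then
  `y = (((qb0*w + qb1*w1 + qb2*w2) >> 16) + 2^15) >> 16`.
* `>> 16` is an arithmetic (floor) shift; only the final rescale to
  counts rounds to nearest (half toward $+\infty$). Saturation is
  saturating, not wrapping, and counted.

These conventions are frozen: the package's correctness claims are
*internal* (streaming vs batch of the same arithmetic), so the exact
rounding convention matters less than its bit-reproducibility, which
the pure-R reference step (`biquad_step()`) and the compiled loops
assert against each other in the test suite. Against a double-precision
Direct-Form-II reference, the fixed-point output stays within a few
counts for inputs at the background-noise scale of extracellular
recordings (the tests bound it by 4 counts at $\sigma = 100$ counts
$\approx 20\ \mu V$).

### State headroom — a known limitation

The Direct-Form-II state sees the input through $1/A(z)$, whose gain
near DC is $(1 + \sqrt2 K + K^2)/4K^2 \approx 120$ at 20 kHz / 300 Hz.
With states at `x << 16` scale, a sub-cutoff component larger than
about 53 µV (273 counts) therefore saturates the 32-bit state store.
Saturation is clamped and counted, and — because both comparison arms
run the identical arithmetic — it never breaks streaming/offline
equivalence; but around clamp transitions the DC rejection is not
clean, and large slow drift (hundreds of µV) produces output artifacts
of tens of µV. The drift-rejection property is accordingly asserted in
the linear range (50 µV drift leaves residuals below 3 counts), and a
companion test pins down the saturating behavior. A hardware revision
would scale the state down (e.g. `x << 12`) or widen the store; both
change the bit-exact contract, so the word lengths here stay as stated.

## The detector

A spike is declared at sample $t-1$ when it is the lowest of the three
samples $t-2, t-1, t$ and lies strictly below the threshold, evaluated
in the count domain (`y1 < y_t`, `y1 <= y2`, `y1 < threshold_counts`).
The asymmetric tie-break makes a flat-bottomed trough fire exactly
once, at its last minimum sample. A detection arms the channel's
refractory counter to `round(refractory_ms * fs / 1000)` samples
(1.5 ms by default); while active, the conditions are not evaluated at
all and the counter decreases once per acquisition loop. Detection
therefore requires two previously seen samples, and consecutive events
on a channel are always separated by more than the refractory period.
The event timestamp is the 0-based per-channel ordinal of the peak
sample $t-1$.

Thresholds are configured in µV and converted once to counts via the
ADC scale (0.195 µV/count, the LSB of the amplifier family the
datapath targets); the filter's unity passband gain keeps the scales
comparable.

## The stream format and decoder

Frames are delimited by a fixed 64-bit synchronization word; the
format (16-byte header, per-frame sync + frame index + channel-major
samples + optional spike-flag bitmap, all little-endian) is specified
byte-exactly in `inst/docs/format.md`. A word-level Moore state
machine (`fsm_step()`) defines decoding: outputs depend only on the
post-transition state, and the byte-level production decoder is its
left-fold on well-formed streams, which the tests assert on randomized
streams. On corruption the decoder trusts frame boundaries while
synchronized (so sample bytes mirroring sync fragments cannot cause a
false resync), scans byte-by-byte after a boundary mismatch, counts
one resynchronization event per corrupted region, and never emits
samples from skipped bytes.

## Timing model

The supported sampling rates pair with fixed system clocks —
30 kHz/84 MHz, 25 kHz/70 MHz, 20 kHz/56 MHz — all giving
$2800$ cycles per frame. With the default pipeline depth of 20 cycles
per channel (chosen to be consistent with the printed per-frame budget
and latencies of such controllers; configurable), 128 channels use
2560 of the 2800 available cycles, so full capacity is feasible with
margin:

```{r}
eng <- engine_config(20000, detector_config(-50, 1.5, 20000),
                     quantize_biquad(design_highpass_butterworth(20000, 300)))
cycle_budget(eng, 128)
```

Worst-case detection latency is the time to acquire the two samples
that must follow a peak before the three-sample rule can confirm it,
plus the serial pipeline's processing time:

```{r}
latency_model(eng)$total_us
```

At 20 kHz / 56 MHz this is 100.357 µs; at 25 kHz / 70 MHz, 80.286 µs.
At 30 kHz the two-sample acquisition alone is 66.67 µs, so any model
of the form "two samples + positive processing time" exceeds a
sub-66.67 µs figure; the model here reports 66.9 µs and only the
20 kHz bound is treated as normative.

## The synthetic recordings

Because raw in vivo data are not redistributable, every test input is
synthesized with known ground truth. Each channel is white Gaussian
noise (σ typically 10–20 µV, matching quiet extracellular baselines)
plus a single low-frequency drift sinusoid with random phase, plus a
stereotyped negative-going action-potential template (difference of
two Gaussians, peak 50–300 µV, ~1 ms) added at spike times drawn from
a Poisson process with dead time. Deliberate simplifications:

* The generator's dead time (2 ms) exceeds the detector's refractory
  period (1.5 ms), so template overlap never confounds the
  streaming-vs-offline comparison.
* Noise is white and uncorrelated across channels; real recordings
  have colored spectra, shared references and cross-channel
  correlation. Passing tests therefore demonstrate the *datapath's*
  correctness, not detection performance on real tissue — the
  package's validation metric is deliberately real-time-vs-offline
  agreement, not sensitivity against ground truth (ground truth is
  exposed for auxiliary diagnostics only).
* Template shape does not vary across a probe and there is no
  electrode model.

Each channel draws from its own RNG substream, derived from the master
seed by a fixed counter scheme (`master + 1000003 * (16*hs + ch + 1)`,
mod $2^{31}-1$), so adding channels never perturbs existing ones and
every artifact is bit-reproducible from a single seed.

One interaction worth knowing: the 300 Hz highpass attenuates broad,
slow waveforms, so a symmetric triangular "spike" of ≥ 1 ms keeps less
than 60% of its raw peak after filtering and is not detectable at a
threshold of 60% of that raw peak. The alignment property (noiseless
spike detected exactly at its ground-truth index) is therefore
asserted with the biphasic template and with short (≤ 0.6 ms)
triangles, which retain their peak.

## The validation protocol

The comparison protocol mirrors a 6-subject × 32-channel × 3-threshold
design: per synthetic animal, a 2 × 16-channel recording at 20 kHz is
generated (rates 2–10 Hz, σ 10–20 µV, peaks −250…−60 µV, drift
100–300 µV at 0.5–5 Hz, drawn per animal from its seed), encoded,
processed by the streaming engine at thresholds −50/−70/−90 µV, and
compared per channel with the offline reference (batch fixed-point
filter, then batch detector). Each cell reports the streaming count
$v_o$, the offline count $v_e$, the percentage error
$\delta = 100\,(v_o - v_e)/v_e$, the accuracy
$E_{acc} = 100 - \delta$, and whether the spike *indices* are
element-wise identical. Means are unweighted over all cells. Two
silent arms compare as a perfect match ($\delta = 0$ by convention); a
nonzero streaming count against a zero offline count would be flagged
and excluded from means with a warning — with the shared-automaton
design this cannot occur, and any non-identical cell is a
build-breaking defect.

```{r, eval = FALSE}
report <- run_protocol(n_animals = 6, duration_s = 60, master_seed = 42)
report$mean_e_acc_pct   # 100
report$mean_delta_pct   # 0
```

The acceptance script (`scripts/acceptance.R`) runs this at full scale
(6 × 32 × 3 cells, 60 s per animal, ~5 minutes on one CPU); the test
suite runs the same 6 × 32 × 3 design at 5 s per animal, which
compares a few thousand spikes per threshold — the comparison is
per-sample exact, so duration only sets how many events are compared.

## Numerical and degenerate-input choices

* Coefficient quantization rounds half away from zero; the output
  rescale rounds half toward $+\infty$; both are frozen, documented
  conventions (hardware may equally truncate — the equivalence claims
  are internal either way).
* Filter and detector states initialize to zero on every channel.
* Int32 saturation clamps at $\pm(2^{31}-1)$ (symmetric, avoiding the
  sentinel R reserves for missing integers).
* Empty traces, empty payloads, silent channels and zero-event streams
  all round-trip as empty-but-valid objects.
* A template overlapping the end of a trace is truncated at the
  boundary; its ground-truth index is kept.
* Duplicate or non-monotone frame indices are passed through: the
  frame index is informative, and event ordinals count decoded frames.

## Known limitations

* The state-headroom saturation described above bounds the usable
  sub-cutoff dynamic range to ~±53 µV at 20 kHz/300 Hz.
* The cycle/latency figures are a budget model of a serial datapath,
  not a cycle-accurate simulation of any specific FPGA.
* The white-noise generator does not model colored noise, correlated
  channels, electrode drift nonstationarity, or spike-shape
  variability; conclusions about detection sensitivity on real data
  are out of scope by design.
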