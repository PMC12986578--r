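---
title: "Time-frequency analysis of nonstationary EMG bursts with emgtf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency analysis of nonstationary EMG bursts with emgtf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgtf)
```

## The problem

During locomotion, a muscle such as the rat biceps femoris fires in short
bursts of roughly 250 ms, one per step. These bursts are strongly
nonstationary: the spectral content during motor-unit recruitment differs
from the sustained plateau and from derecruitment, and pathological states
shift these dynamics in a phase-dependent way. A single power spectrum per
burst throws that structure away. `emgtf` therefore computes *time-resolved*
spectral descriptors with three complementary methods, averages them within
three physiologically motivated contraction phases, and compares the
phase-resolved features across experimental groups.

All sampling defaults follow a typical chronic-recording setup: 2000 Hz
sampling, an analysis band of 30-500 Hz and a 50 Hz power-line notch.

## Preprocessing and burst segmentation

`bandpass_notch()` applies a 4th-order Butterworth band-pass and a biquad
notch (Q = 30), both forward-backward. Zero-phase filtering matters here:
a causal filter would delay burst onsets by several milliseconds and bias
every phase-resolved feature.

`detect_bursts()` thresholds a 10 ms moving-RMS envelope at
`median + 5 * MAD`. The median/MAD pair was chosen over mean/SD because the
amplitude distribution of a bursting recording is dominated by the bursts
themselves; robust location/scale keeps the threshold anchored to the
baseline, and makes detection exactly invariant to rescaling the
recording. Runs shorter than 100 ms are discarded (a locomotor burst is
never that short), runs separated by less than 30 ms are merged (envelope
dips within one contraction), and boundaries are refined outward to the
nearest half-threshold crossing so that slow onset ramps are not clipped.
All four parameters are exposed.

`partition_phases()` fixes the sustained phase at 80-150 ms from onset and
derives recruitment (onset to 80 ms) and derecruitment (150 ms to offset)
from it — the only reading consistent with a three-phase vocabulary around
a fixed sustained window. The boundary convention (recruitment half-open,
sustained closed, derecruitment left-open) makes the three index sets an
exact partition: at 2000 Hz a 250 ms burst splits into 160 + 141 + 199
samples. Bursts shorter than 150 ms are flagged and excluded rather than
raising an error, since a session-level analysis should not die on one
malformed contraction.

## Spectrograms

`stft_spectrogram()` uses Hamming-windowed frames, 80 ms window / 75 ms
overlap / 160-point FFT by default (12.5 Hz bins at 2000 Hz), with a
30 ms / 25 ms / 64-point alternative trading frequency resolution for
temporal resolution. The 64-point FFT for the short window is our choice
(the nearest convenient length above the 60-sample window); it is
configurable. Two deliberate conventions:

* **No zero-padding of the burst.** A frame is emitted only where the
  window is fully supported, so estimates near the edges are never diluted
  by out-of-burst zeros. The first and last frame centers sit at half a
  window from the edges — 40 ms for the 80 ms window, 15 ms for the 30 ms
  window — and this "edge region" width is tested as an analytic property
  of the implementation, for any window length.
* **Mass-centered median interpolation.** `F_median` interpolates the
  cumulative power between bin centers treating each bin's mass as located
  at its center. This makes a single-bin spectrum return exactly that
  bin's frequency and a flat 30-500 Hz band return the 265 Hz midpoint,
  and reduces the 12.5 Hz grid quantization. Nearest-bin behavior can be
  recovered by comparing against the grid, but interpolation is the
  default.

Power is normalized so that the per-frame sum over the one-sided spectrum
equals the windowed-segment energy (a Parseval identity kept to 1e-6 in
the tests); `F_mean`/`F_median` are scale-invariant, so this choice is
internal.

## Bump-wavelet CWT

`bump_cwt()` implements the transform in the frequency domain:
`W(s, ·) = ifft(x_hat * conj(psi_hat(s omega)))` with
`psi_hat(xi) = exp(1 - 1/(1 - ((xi - mu)/sigma)^2))` on `|xi - mu| < sigma`,
zero elsewhere. Defaults mu = 5, sigma = 0.6 (the de-facto defaults of
common wavelet toolboxes; both exposed). Because the support is symmetric
about mu, the peak-frequency and center-of-mass scale-to-frequency
conversions coincide; we use the peak convention `f = mu/(2 pi s)`, which
is trivial to verify with tones. Scales form a geometric grid, 16 voices
per octave spanning 30-500 Hz with the top frequency kept on the grid.

The signal is zero-extended (never reflected) before the FFT. Reflection
would reduce visible edge artifacts but would also invalidate the cone of
influence as a *bound* on edge contamination; with zero extension the COI
semantics are exact. The COI itself uses `t_e(s) = s * tau_e`, where
`tau_e` is the two-sided e-folding half-width of the mother wavelet's time
envelope. The Bump wavelet has no closed-form time expression, so `tau_e`
is computed once numerically (inverse FFT of `psi_hat` on a dense grid;
about 5.47 for the defaults) and cached. Scales for which the burst is
shorter than `2 t_e(s)` are fully masked — on a 250 ms burst this
genuinely removes the lowest analysis frequencies, which is the honest
statement of what a wavelet can estimate there.

## NA-MEMD and Hilbert features

`na_memd()` appends white Gaussian noise channels (3 by default) and runs
one multivariate EMD over all channels, so that mode k means the same
oscillatory regime in every channel (the alignment property used for
cross-subject comparison). Design choices, all exposed as parameters:

* Direction vectors: a Hammersley low-discrepancy sequence mapped to the
  unit hypersphere through the Gaussian radial map; 64 directions by
  default, raised automatically (with a warning) to at least twice the
  channel count.
* Envelopes: natural cubic splines through the multivariate signal at the
  projection extrema, with two extrema mirrored beyond each edge to tame
  boundary divergence. The sifting inner loop is implemented in C++
  (`src/memd_core.cpp`) — it is the computational bottleneck of the whole
  package.
* Stop criterion: Rilling-style three-threshold rule (0.05, 0.5, 0.05) on
  the normalized local mean, with a 1000-iteration safety cap per mode.
* Noise amplitude: SD equal to 1.0 times the mean signal-channel SD. No
  reference value exists for this ratio; decomposition structure is known
  to be sensitive to it, so it is prominently exposed
  (`noise_sd_ratio`) and recorded in the pipeline manifest.
* Pooling: one joint decomposition per run over all loaded channels,
  truncated to the common minimum length. `max_modes` defaults to 10 and
  analyses focus on modes 2-4 (`modes_of_interest`), where burst-band
  content concentrates at 2000 Hz.

`hilbert_if_ie()` computes the analytic signal per mode via the
frequency-domain Hilbert multiplier; instantaneous frequency is the
central-difference derivative of the unwrapped phase, median-smoothed over
5 ms and clipped to `[0, fs/2]`. Where the analytic amplitude falls below
1% of the mode RMS the frequency is set to missing: the phase derivative
of a near-zero analytic signal is numerically meaningless, and a handful
of such samples would otherwise dominate phase averages. Instantaneous
energy (squared amplitude) has no such floor.

`segment_imfs()` slices the Hilbert series at burst annotations and emits,
per burst, mode and phase, the mean instantaneous frequency over
non-missing samples and the mean instantaneous energy — the two features
entering the multivariate statistics.

## Statistics

Observation unit is the individual contraction, deliberately accepting
pseudo-replication in exchange for power on large burst counts; a
`unit = "subject"` option aggregates to per-subject means for the
conservative analysis. For spectral sources, each metric x phase cell gets
a one-way ANOVA with Tukey-Kramer post hocs (studentized range, valid for
unequal group sizes; with equal n it reduces to classic HSD, which the
tests verify against a `ptukey` oracle). For IMF sources, a MANOVA on the
bivariate (frequency, energy) response gates per-variable follow-up
ANOVAs; the family for the Holm step-down correction is *all* imf x phase
x metric ANOVAs spawned in one battery run — the widest defensible family,
logged in the output. Wilks' Lambda is the default multivariate statistic
(Pillai available). Because the step-down Holm procedure and the
single-step Bonferroni differ and both appear in common practice, both are
implemented (`correction =`), with Holm the default. No multiplicity
correction is applied across the spectral-source ANOVAs by default.

Type-I error calibration of both tests is part of the acceptance suite
(1000 null simulations each; rejection rate required within
[0.035, 0.065] at alpha = 0.05).

## The synthetic generator

`generate_burst()` synthesizes a burst as band-shaped Gaussian noise:
white noise is filtered per 20 ms Hann sub-window by a Gaussian band
response centered on a condition's *centroid trajectory* (with a
*bandwidth trajectory* as its width), overlap-added, multiplied by an
asymmetric envelope (60 ms half-Hann rise, 80 ms decay), and optionally
augmented with a Gaussian-windowed wideband pulse (20 ms FWHM). Filtered
noise, not sums of sinusoids, because EMG is broadband and stochastic: the
validation would be meaningless on line spectra. Trajectories are
parameterized in normalized burst time (0 = onset, 1 = offset) so that
duration jitter rescales, rather than distorts, the spectral program.

The five presets (`default_profiles()`) emulate progressive spectral
compression: time-averaged centroids 380 > 330 > 307.5 > 297.5 > 248 Hz
for control through week6, with week4/week5 nearly tied, mildly increasing
within-burst trends for weeks 3-5, a centroid sag at the edges plus a
wideband transient at 50 ms for week6, and a 250 ms mean burst duration
(SD 20 ms) everywhere. Inter-burst intervals are 400 +/- 60 ms (step-cycle
order of magnitude) and the inter-burst baseline is Gaussian with SD 5% of
the burst RMS — small enough to be realistic, large enough that burst
detection is not trivial. Burst amplitudes are arbitrary units: absolute
EMG voltage calibration is hardware-specific and nothing downstream
depends on it.

What the generator does *not* emulate: motor-unit action potential trains
and their synchronization, conduction-velocity changes, electrode and
movement artifacts, inter-subject variability in burst morphology, or
gait-speed modulation. A passing benchmark therefore shows that the
analysis chain recovers programmed spectro-temporal structure from
realistic broadband bursts — not that it would be equally sensitive on any
particular real dataset.

## Problem sizes and numerical choices

The packaged benchmark runs 5 conditions x 200 bursts per condition for
the spectral analyses and truncates each subject's record to 10 s for the
pooled NA-MEMD stage — sizes chosen to exercise every stage at full
statistical strength while keeping a complete run in the minutes range on
a single core. Unit tests use smaller fixtures (1-4 s, 16 directions).
Key tolerances: EMD reconstruction is exact by construction (tested at
1e-8 relative, observed near machine epsilon); two-tone mode recovery is
asserted at +/-10% (EMD edge effects); spectral Monte-Carlo checks at
+/-10%; Hilbert identities at 0.5 Hz / 2%. Degenerate inputs are defined,
not fatal: all-zero bursts yield zero maps, all-zero modes yield missing
frequencies, empty trajectory columns yield missing metrics, and
too-short bursts are flagged.

The pipeline (`run_all()`) derives all per-stage seeds from one master
seed through a single `sample.int` draw, so any stage can be re-run in
isolation and a rerun with the same config is bit-identical.

## Known limitations

* EMD has no uniqueness theory; mode counts and contents depend on the
  noise realization, the direction count and the stop thresholds. The
  alignment across channels holds by construction, but comparisons across
  *runs* require the same seed and parameters.
* The CWT trajectory values are computed within the cone of influence
  only; near burst edges they are averages over the surviving (higher)
  frequencies and read systematically higher than spectrogram values
  there. This mirrors the behavior of any COI-masked wavelet analysis and
  should be kept in mind when comparing methods near onsets/offsets.
* Tukey p-values assume independent observations; with bursts as the
  unit, within-subject correlation makes them anti-conservative. Use
  `unit = "subject"` when subjects, not bursts, are the inferential
  target.
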