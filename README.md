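# emgtf

Comparative time–frequency characterization of highly nonstationary EMG
bursts.

Locomotor electromyography produces short (~250 ms) bursts whose spectral
content changes *within* a single contraction, so classical whole-burst
mean/median-frequency estimates are biased and blind to phase-dependent
effects. `emgtf` implements, in one tested R package, the three
complementary analyses used to study this problem — short-time Fourier
spectrograms, a continuous wavelet transform with the Bump mother wavelet,
and noise-assisted multivariate empirical mode decomposition (NA-MEMD) with
Hilbert instantaneous frequency/energy — together with burst detection,
contraction-phase partitioning, phase-resolved group statistics, and a
synthetic locomotor-EMG generator for validating the whole chain. It is
aimed at electrophysiologists and biomedical signal-processing researchers
comparing time–frequency methods on bursting muscle activity (e.g. across
stages of a motor-impairment model).

## Methods at a glance

**Spectrogram.** `SPEC_x(τ, f) = |STFT_x(τ, f)|²` with a Hamming window
`w(t − τ)`; defaults are an 80 ms window, 75 ms overlap and a 160-point FFT
at 2000 Hz (12.5 Hz bins), plus a 30 ms / 25 ms / 64-point alternative for
better temporal resolution. Frames are computed only where fully supported,
so a window of length `L` leaves unsupported edge regions of `L/2` at each
end of a burst (40 ms for the 80 ms window, 15 ms for the 30 ms window).
Per frame, `F_mean = Σ f·P(f) / Σ P(f)` and `F_median` is the half-power
frequency, interpolated between grid bins.

**CWT.** `W_x(τ, s) = s^{-1/2} ∫ x(t) ψ*((t−τ)/s) dt` with the analytic
Bump wavelet `ψ̂(ξ) = exp(1 − 1/(1 − ((ξ−μ)/σ)²))` on `|ξ−μ| < σ`
(defaults μ = 5, σ = 0.6), wavelet energy `P_x(τ, f) = |W_x(τ, s(f))|²/s`,
scale↔frequency via the peak convention `f = μ/(2πs)` on a geometric grid
(16 voices/octave, 30–500 Hz). A cone of influence derived from the
wavelet's numerically computed e-folding time width masks edge-contaminated
cells.

**NA-MEMD + Hilbert.** White-noise channels (3 by default, SD equal to the
mean signal SD) are appended to the multichannel matrix and a *single*
multivariate EMD is run over all channels: each sifting iteration projects
the signal onto 64 Hammersley-sequence directions on the unit hypersphere,
interpolates channel envelopes at the projection extrema with cubic
splines, and subtracts the direction-averaged local mean until a
Rilling-style criterion (0.05, 0.5, 0.05) is met. This aligns mode indices
across channels and mitigates mode mixing. Each IMF then yields
instantaneous frequency (derivative of the unwrapped analytic phase) and
instantaneous energy (squared analytic amplitude).

**Phase-resolved statistics.** Bursts are split into recruitment
(onset–80 ms), sustained (80–150 ms) and derecruitment (150 ms–offset)
phases. Spectral metrics are compared across groups with one-way ANOVA and
Tukey–Kramer post hocs; IMF frequency–energy pairs with a MANOVA gate
(Wilks' Λ), Holm-corrected follow-up ANOVAs, then post hocs.

## Worked example

```r
library(emgtf)

profiles <- default_profiles()                      # control, week3..week6 presets
burst <- generate_burst(profiles$week6, fs = 2000, seed = 42, duration_ms = 250)
map <- stft_spectrogram(burst, window_ms = 80, overlap_ms = 75, nfft = 160)
print(map)
#> <tf_map:stft> 35 frames x 81 freqs; t = [40.0, 210.0] ms; f = [0.0, 1000.0] Hz; 100% valid

feats <- phase_spectral_features(burst, map, source = "stft80")
feats[feats$metric == "f_median", c("phase", "metric", "value")]
#>          phase   metric value
#>    recruitment f_median 330.7
#>      sustained f_median 245.1
#>  derecruitment f_median 241.1
```

The frame centers run from 40 to 210 ms: the 80 ms window cannot be
supported in the first or last 40 ms of a 250 ms burst. The week6 preset's
median frequency sits low (~245 Hz) in the sustained/derecruitment phases —
its programmed spectral compression — while the recruitment value is
inflated by the preset's wideband ~50 ms energy transient. The same seed
under the control preset reads 407.9 / 407.9 / 374.8 Hz across the three
phases.
For the wavelet view:

```r
cwt_map <- bump_cwt(burst, bump_wavelet(mu = 5, sigma = 0.6))
print(cwt_map)
#> <tf_map:cwt> 500 frames x 66 freqs; t = [0.0, 249.5] ms; f = [30.0, 500.0] Hz; 61% valid
```

— one coefficient per sample, with 39% of cells masked by the cone of
influence.

The full chain (simulate → filter → detect bursts → STFT/CWT/NA-MEMD →
feature table → statistics) is one call:

```r
cfg <- run_config(seed = 1, synth = list(bursts_per_subject = 40L))
res <- run_all(cfg, "results/run1")   # writes features.csv, stats_*.csv, manifest.json
```

A thin CLI over the same functions is installed at
`system.file("cli", "emgtf.R", package = "emgtf")` with `simulate`,
`segment`, `tf`, `stats` and `run-all` subcommands.

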