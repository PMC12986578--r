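Package: emgtf
Title: Time-Frequency Characterization of Nonstationary EMG Bursts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative time-frequency analysis of highly nonstationary
    electromyographic (EMG) bursts recorded during locomotion. Implements
    short-time Fourier transform spectrograms with edge-validity masking,
    a continuous wavelet transform with the Bump mother wavelet and cone of
    influence, and noise-assisted multivariate empirical mode decomposition
    (NA-MEMD) with Hilbert instantaneous frequency and energy, followed by
    burst detection, contraction-phase partitioning and phase-resolved group
    statistics (ANOVA/Tukey, MANOVA with Holm-corrected follow-up ANOVAs).
    Includes a synthetic locomotor-EMG generator emulating progressive
    spectral compression across experimental conditions, for validation and
    benchmarking of the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
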