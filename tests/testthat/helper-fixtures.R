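# Shared fixtures, built in code at load time.

make_tone_burst <- function(freq = 200, dur_s = 0.25, fs = 2000, amp = 1) {
  t <- (0:(round(dur_s * fs) - 1)) / fs
  emg_burst(amp * sin(2 * pi * freq * t), fs)
}

# Two channels sharing 50 Hz + 300 Hz tones with different phases/weights.
make_two_tone_recording <- function(dur_s = 4, fs = 2000) {
  t <- (0:(round(dur_s * fs) - 1)) / fs
  x1 <- sin(2 * pi * 50 * t) + sin(2 * pi * 300 * t)
  x2 <- cos(2 * pi * 50 * t + 0.5) + 0.8 * sin(2 * pi * 300 * t + 1)
  emg_recording(cbind(x1, x2), fs,
                data.frame(subject = c("a", "b"), group = NA_character_,
                           is_noise_channel = FALSE))
}

# Mean Hilbert IF per mode averaged over the named channels.
mode_mean_if <- function(hs, channels = NULL) {
  d <- dim(hs$inst_freq_hz)
  if (is.null(channels)) channels <- seq_len(d[1])
  vapply(seq_len(d[2]), function(m)
    mean(hs$inst_freq_hz[channels, m, ], na.rm = TRUE), numeric(1))
}

# Mean Hilbert energy per mode per channel.
mode_mean_energy <- function(hs, channel) {
  d <- dim(hs$inst_energy)
  vapply(seq_len(d[2]), function(m)
    mean(hs$inst_energy[channel, m, ]), numeric(1))
}

# Tidy feature table with groups drawn from given per-group means.
make_feature_table <- function(group_means, n_per_group = 20, sd = 1,
                               metric = "f_median", source = "stft80",
                               phase = "derecruitment", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(group_means), function(g) {
    data.frame(subject = g, group = g, burst_id = seq_len(n_per_group),
               phase = phase, source = source, metric = metric,
               value = rnorm(n_per_group, group_means[[g]], sd),
               stringsAsFactors = FALSE)
  }))
}
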