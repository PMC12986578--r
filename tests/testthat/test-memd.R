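# NA-MEMD unit tests use short fixtures and a reduced direction count
# (>= 2x the channel count) to keep decompositions quick; the direction
# default (64) is exercised in the acceptance suite.

test_that("decomposition is complete and mode-aligned on arbitrary input", {
  set.seed(2)
  fs <- 2000
  X <- cbind(rnorm(3000), rnorm(3000))
  rec <- emg_recording(X, fs)
  imfs <- na_memd(rec, n_directions = 16, seed = 5)
  # every channel (incl. noise) reconstructs exactly
  recon <- apply(imfs$imfs, c(1, 3), sum) + imfs$residual
  d <- dim(imfs$imfs)
  expect_equal(d[1], 5L)  # 2 signal + 3 noise channels
  for (ch in 1:2) {
    relerr <- max(abs(recon[ch, ] - X[, ch])) / max(abs(X[, ch]))
    expect_lt(relerr, 1e-8)
  }
  # the multivariate property: one shared mode count
  expect_true(is.numeric(n_modes(imfs)) && n_modes(imfs) >= 2)
  expect_equal(dim(imfs$imfs)[2], n_modes(imfs))
  expect_equal(sum(imfs$channel_meta$is_noise_channel), 3L)
})

test_that("decomposition is reproducible from its seed", {
  rec <- make_two_tone_recording(dur_s = 1)
  i1 <- na_memd(rec, n_directions = 16, seed = 9)
  i2 <- na_memd(rec, n_directions = 16, seed = 9)
  expect_identical(i1$imfs, i2$imfs)
  i3 <- na_memd(rec, n_directions = 16, seed = 10)
  expect_false(identical(i1$imfs, i3$imfs))
})

test_that("two shared tones separate into the same aligned modes", {
  rec <- make_two_tone_recording(dur_s = 4)
  imfs <- na_memd(rec, n_directions = 16, seed = 7)
  hs <- hilbert_if_ie(imfs)
  # pick, per channel, the two most energetic modes: they must carry the
  # 300 Hz and 50 Hz tones at the same mode indices in both channels
  pick <- function(ch) order(mode_mean_energy(hs, ch), decreasing = TRUE)[1:2]
  p1 <- sort(pick(1)); p2 <- sort(pick(2))
  expect_equal(p1, p2)
  if_ch1 <- vapply(p1, function(m) mean(hs$inst_freq_hz[1, m, ], na.rm = TRUE),
                   numeric(1))
  if_ch2 <- vapply(p1, function(m) mean(hs$inst_freq_hz[2, m, ], na.rm = TRUE),
                   numeric(1))
  hi1 <- max(if_ch1); lo1 <- min(if_ch1)
  expect_lt(abs(hi1 - 300) / 300, 0.10)
  expect_lt(abs(lo1 - 50) / 50, 0.10)
  expect_lt(abs(max(if_ch2) - 300) / 300, 0.10)
  expect_lt(abs(min(if_ch2) - 50) / 50, 0.10)
})

test_that("inputs are validated and low direction counts raised", {
  expect_error(na_memd(emg_recording(matrix(rnorm(3), ncol = 1), 2000)),
               "4 samples")
  rec <- make_two_tone_recording(dur_s = 0.5)
  expect_warning(i <- na_memd(rec, n_directions = 4, seed = 1), "twice")
})

test_that("white-noise modes form a descending frequency cascade", {
  fs <- 2000
  for (rep_seed in 1:10) {
    set.seed(100 + rep_seed)
    rec <- emg_recording(cbind(rnorm(1500), rnorm(1500)), fs)
    imfs <- na_memd(rec, n_directions = 16, seed = 200 + rep_seed)
    hs <- hilbert_if_ie(imfs)
    mif <- mode_mean_if(hs)
    expect_true(all(diff(mif) < 0))
  }
})

test_that("instantaneous frequency of a tone matches the analytic identity", {
  fs <- 2000
  t <- (0:1999) / fs
  x <- sin(2 * pi * 100 * t)
  imfs <- imf_set(array(x, dim = c(1, 1, length(x))),
                  matrix(0, 1, length(x)), fs,
                  data.frame(subject = "s", group = NA,
                             is_noise_channel = FALSE))
  hs <- hilbert_if_ie(imfs)
  inner <- 21:1980   # away from 10 ms edges
  expect_true(all(abs(hs$inst_freq_hz[1, 1, inner] - 100) <= 0.5))
})

test_that("instantaneous energy of an AM tone tracks the squared envelope", {
  fs <- 2000
  t <- (0:3999) / fs
  a <- 1 + 0.5 * sin(2 * pi * 2 * t)
  x <- a * cos(2 * pi * 100 * t)
  imfs <- imf_set(array(x, dim = c(1, 1, length(x))),
                  matrix(0, 1, length(x)), fs,
                  data.frame(subject = "s", group = NA,
                             is_noise_channel = FALSE))
  hs <- hilbert_if_ie(imfs)
  inner <- 101:3900
  relerr <- abs(hs$inst_energy[1, 1, inner] - a[inner]^2) / a[inner]^2
  expect_lt(max(relerr), 0.02)
})

test_that("an all-zero mode has zero energy and undefined frequency", {
  imfs <- imf_set(array(0, dim = c(1, 1, 500)), matrix(0, 1, 500), 2000,
                  data.frame(subject = "s", group = NA,
                             is_noise_channel = FALSE))
  hs <- hilbert_if_ie(imfs)
  expect_true(all(hs$inst_energy == 0))
  expect_true(all(is.na(hs$inst_freq_hz)))
})

test_that("marginal spectra stagger high-to-low with bracketing ranges", {
  rec <- make_two_tone_recording(dur_s = 4)
  imfs <- na_memd(rec, n_directions = 16, seed = 7)
  ms <- imf_marginal_spectra(imfs)
  # dominant ranges ordered high -> low along the mode index
  expect_true(all(diff(ms$dominant$f_peak_hz) <= 0))
  # the tone-carrying modes bracket their tones
  hs <- hilbert_if_ie(imfs)
  en <- mode_mean_energy(hs, 1)
  m300 <- order(en, decreasing = TRUE)[1:2]
  df <- ms$freq[2] - ms$freq[1]   # Welch grid spacing
  for (m in m300) {
    tone <- if (ms$dominant$f_peak_hz[m] > 150) 300 else 50
    expect_lte(ms$dominant$f_lo_hz[m] - df, tone)
    expect_gte(ms$dominant$f_hi_hz[m] + df, tone)
  }
})

test_that("noise assistance does not worsen mode mixing at matched seeds", {
  # synthetic EMG-like fixture: one subject, a few bursts
  spec <- session_spec(default_profiles()["control"], bursts_per_subject = 4,
                       seed = 31)
  sess <- generate_session(spec)
  rec <- emg_recording(sess$recordings[[1]]$samples[1:6000, , drop = FALSE],
                       2000, sess$recordings[[1]]$channel_meta)
  overlap_index <- function(imfs) {
    dom <- imf_marginal_spectra(imfs)$dominant
    n <- nrow(dom)
    ov <- vapply(seq_len(n - 1), function(k) {
      lo <- max(dom$f_lo_hz[k + 1], dom$f_lo_hz[k])
      hi <- min(dom$f_hi_hz[k + 1], dom$f_hi_hz[k])
      wid <- min(dom$f_hi_hz[k] - dom$f_lo_hz[k],
                 dom$f_hi_hz[k + 1] - dom$f_lo_hz[k + 1])
      if (wid <= 0) return(0)
      max(0, hi - lo) / wid
    }, numeric(1))
    mean(ov)
  }
  with_noise <- na_memd(rec, n_noise_channels = 3, n_directions = 16, seed = 8)
  without <- na_memd(rec, n_noise_channels = 0, n_directions = 16, seed = 8)
  expect_lte(overlap_index(with_noise), overlap_index(without) + 1e-9)
  # successive-mode dominant ranges mostly disjoint on the noisy fixture
  expect_lt(overlap_index(with_noise), 0.5)
})

test_that("phase-resolved IMF features average piecewise-constant series", {
  fs <- 2000
  n <- 600   # 300 ms burst at [0.0, 0.3) s
  inst_f <- array(150, dim = c(1, 2, n))
  inst_e <- array(1, dim = c(1, 2, n))
  inst_e[1, 2, ] <- c(rep(1, 160), rep(3, n - 160))  # 1 before 80 ms, 3 after
  hs <- hilbert_series(inst_f, inst_e, fs,
                       data.frame(subject = "s1", group = "control",
                                  is_noise_channel = FALSE))
  ann <- data.frame(subject = "s1", group = "control", burst_id = 1L,
                    onset_s = 0, offset_s = 0.3)
  feats <- segment_imfs(hs, ann, modes = 1:2)
  f_rows <- feats[feats$metric == "inst_freq_mean", ]
  expect_true(all(f_rows$value == 150))
  e2 <- feats[feats$source == "imf2" & feats$metric == "inst_energy_mean", ]
  expect_equal(e2$value[e2$phase == "recruitment"], 1)
  expect_equal(e2$value[e2$phase == "sustained"], 3)
  expect_equal(e2$value[e2$phase == "derecruitment"], 3)
  # annotations outside the record are skipped silently
  ann_bad <- rbind(ann, data.frame(subject = "s1", group = "control",
                                   burst_id = 2L, onset_s = 5, offset_s = 5.3))
  expect_equal(nrow(segment_imfs(hs, ann_bad, modes = 1:2)), nrow(feats))
})
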