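test_that("default presets encode progressive spectral compression", {
  p <- default_profiles()
  expect_named(p, c("control", "week3", "week4", "week5", "week6"))
  u <- seq(0, 1, length.out = 201)
  # control centroid exceeds week6 centroid at every normalized time
  expect_true(all(p$control$centroid_trajectory(u) >
                    p$week6$centroid_trajectory(u)))
  # time-averaged centroid strictly decreasing along the lesion ordering
  avg <- vapply(p, function(pr) mean(pr$centroid_trajectory(u)), numeric(1))
  expect_true(all(diff(avg) < 0))
  # week4 and week5 nearly tied relative to the other gaps
  expect_lt(avg["week4"] - avg["week5"], avg["week5"] - avg["week6"])
  # all centroids inside the 30-500 Hz band
  for (pr in p) expect_true(all(pr$centroid_trajectory(u) >= 30 &
                                  pr$centroid_trajectory(u) <= 500))
  # early transient only in the most-lesioned preset, centered at 50 ms
  expect_gt(p$week6$transient_gain, 0)
  expect_equal(p$week6$transient_time_ms, 50)
  for (nm in c("control", "week3", "week4", "week5"))
    expect_equal(p[[nm]]$transient_gain, 0)
  # mean burst duration 250 ms everywhere
  for (pr in p) expect_equal(pr$burst_duration_ms[[1]], 250)
})

test_that("profile constructor rejects out-of-band centroids and bad gains", {
  expect_error(condition_profile("x", function(u) rep(20, length(u))), "30")
  expect_error(condition_profile("x", function(u) rep(600, length(u))), "500")
  expect_error(condition_profile("x", function(u) rep(200, length(u)),
                                 transient_gain = -1), "non-negative")
})

test_that("a zero envelope yields an all-zero burst", {
  pr <- condition_profile("null", function(u) rep(200, length(u)),
                          envelope = function(t_ms, d) rep(0, length(t_ms)))
  b <- generate_burst(pr, 2000, seed = 1, duration_ms = 250)
  expect_true(all(b$samples == 0))
})

test_that("burst generation validates the sampling rate", {
  pr <- default_profiles()$control
  expect_error(generate_burst(pr, fs = 500), "fs")
})

test_that("generated bursts hit the programmed sustained-phase centroid", {
  pr <- default_profiles()$control
  cents <- vapply(1:150, function(s) {
    b <- generate_burst(pr, 2000, seed = s, duration_ms = 250)
    w <- emgtf:::welch_psd(b$samples[161:301], 2000, 128)
    emgtf:::psd_centroid(w$freq, w$psd, c(30, 500))
  }, numeric(1))
  # target: centroid trajectory averaged over the sustained phase (80-150 ms)
  target <- mean(pr$centroid_trajectory(seq(80, 150, by = 5) / 250))
  expect_lt(abs(mean(cents) - target) / target, 0.10)
})

test_that("the week6-style transient adds energy in a 20 ms window at 50 ms", {
  base <- condition_profile("plain", function(u) rep(250, length(u)))
  trans <- condition_profile("trans", function(u) rep(250, length(u)),
                             transient_gain = 1.5, transient_time_ms = 50)
  fs <- 2000
  win <- (round(0.040 * fs)):(round(0.060 * fs))   # 40-60 ms
  e <- vapply(1:100, function(s) {
    b0 <- generate_burst(base, fs, seed = s, duration_ms = 250)
    b1 <- generate_burst(trans, fs, seed = s, duration_ms = 250)
    c(mean(b0$samples[win]^2), mean(b1$samples[win]^2))
  }, numeric(2))
  expect_gt(mean(e[2, ]), mean(e[1, ]))
})

test_that("sessions are reproducible and annotations non-overlapping", {
  spec <- session_spec(default_profiles()["control"], bursts_per_subject = 10,
                       seed = 21)
  s1 <- generate_session(spec)
  s2 <- generate_session(spec)
  expect_identical(s1$recordings[[1]]$samples, s2$recordings[[1]]$samples)
  expect_identical(s1$annotations, s2$annotations)
  ann <- s1$annotations
  expect_equal(nrow(ann), 10L)
  expect_true(all(ann$offset_s > ann$onset_s))
  expect_true(all(ann$onset_s[-1] >= ann$offset_s[-nrow(ann)]))
})

test_that("a zero-burst spec produces baseline only", {
  spec <- session_spec(default_profiles()["control"], bursts_per_subject = 0,
                       session_length_s = 2, seed = 3)
  s <- generate_session(spec)
  expect_equal(nrow(s$annotations), 0L)
  expect_lt(stats::sd(s$recordings[[1]]$samples), 0.2)
})

test_that("the Nyquist margin and session capacity are enforced", {
  expect_error(session_spec(default_profiles(), fs = 800), "Nyquist")
  expect_error(session_spec(default_profiles()["control"],
                            bursts_per_subject = 100, session_length_s = 5),
               "too short")
})

test_that("generated bursts preserve the preset centroid ordering", {
  profs <- default_profiles()
  med <- vapply(profs, function(pr) {
    mean(vapply(1:60, function(s) {
      b <- generate_burst(pr, 2000, seed = s, duration_ms = 250)
      tr <- spectral_trajectory(stft_spectrogram(b))
      mean(tr$f_median_hz, na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(rank(-med)), 1:5)  # control > week3 > week4 > week5 > week6
})
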