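#' Condition profile for the synthetic locomotor-EMG generator
#'
#' A condition profile describes the spectro-temporal program of a burst for
#' one experimental condition: the spectral-centroid trajectory and
#' half-bandwidth trajectory as functions of normalized burst time (0 =
#' onset, 1 = offset), the amplitude envelope as a function of time in ms
#' and burst duration, an optional early wideband energy transient, and the
#' burst-duration / inter-burst-interval distributions.
#'
#' @param name condition label.
#' @param centroid_trajectory function(u) of normalized time in `[0, 1]`
#'   returning the target spectral centroid in Hz; values must stay within
#'   the 30-500 Hz analysis band.
#' @param bandwidth_trajectory function(u) returning the spectral
#'   half-bandwidth (Gaussian sigma) in Hz.
#' @param envelope function(t_ms, duration_ms) returning a non-negative
#'   amplitude gain, zero outside `[0, duration_ms]`.
#' @param transient_gain non-negative amplitude of the added early wideband
#'   transient, relative to the plateau noise amplitude (0 disables it).
#' @param transient_time_ms center of the transient, ms from burst onset.
#' @param burst_duration_ms length-2 numeric `c(mean, sd)` in ms.
#' @param inter_burst_interval_ms length-2 numeric `c(mean, sd)` in ms.
#' @return An object of class `condition_profile`.
#' @export
condition_profile <- function(name,
                              centroid_trajectory,
                              bandwidth_trajectory = function(u) rep(55, length(u)),
                              envelope = default_envelope,
                              transient_gain = 0,
                              transient_time_ms = 50,
                              burst_duration_ms = c(mean = 250, sd = 20),
                              inter_burst_interval_ms = c(mean = 400, sd = 60)) {
  stopifnot(is.function(centroid_trajectory), is.function(bandwidth_trajectory),
            is.function(envelope))
  if (transient_gain < 0) stop("transient_gain must be non-negative")
  u <- seq(0, 1, length.out = 101)
  fc <- centroid_trajectory(u)
  if (any(fc < 30) || any(fc > 500))
    stop("centroid trajectory must stay within [30, 500] Hz")
  structure(
    list(name = name,
         centroid_trajectory = centroid_trajectory,
         bandwidth_trajectory = bandwidth_trajectory,
         envelope = envelope,
         transient_gain = transient_gain,
         transient_time_ms = transient_time_ms,
         burst_duration_ms = burst_duration_ms,
         inter_burst_interval_ms = inter_burst_interval_ms),
    class = "condition_profile"
  )
}

#' Default burst amplitude envelope
#'
#' Half-Hann rise over the first 60 ms, plateau at 1, half-Hann decay over
#' the last 80 ms; zero outside `[0, duration_ms]`. The asymmetric shape
#' mimics the faster recruitment / slower derecruitment of locomotor bursts.
#'
#' @param t_ms time from burst onset in ms (vectorized).
#' @param duration_ms burst duration in ms.
#' @return amplitude gain in `[0, 1]`.
#' @export
default_envelope <- function(t_ms, duration_ms) {
  rise <- 60
  fall <- 80
  g <- numeric(length(t_ms))
  inside <- t_ms >= 0 & t_ms <= duration_ms
  tt <- t_ms[inside]
  gi <- rep(1, length(tt))
  r <- tt < rise
  gi[r] <- sin(pi * tt[r] / (2 * rise))^2
  f <- tt > duration_ms - fall
  gi[f] <- pmin(gi[f], sin(pi * (duration_ms - tt[f]) / (2 * fall))^2)
  g[inside] <- gi
  g
}

#' Default condition presets
#'
#' Five presets (control, week3 ... week6) emulating progressive spectral
#' compression: time-averaged centroid ordering control > week3 > week4 >
#' week5 > week6 with week4 and week5 nearly tied, the control centroid
#' above the week6 centroid at every normalized time, a mean burst duration
#' of 250 ms for all conditions, and a wideband ~50 ms energy transient only
#' in the most-lesioned (week6) preset. Weeks 3-5 carry a mildly increasing
#' within-burst centroid trend and week6 a centroid sag at burst edges,
#' echoing the phenomenology the presets emulate.
#'
#' @return named list of [condition_profile()] objects in the order control,
#'   week3, week4, week5, week6.
#' @export
default_profiles <- function() {
  list(
    control = condition_profile(
      "control",
      centroid_trajectory = function(u) 390 - 20 * u,
      bandwidth_trajectory = function(u) rep(55, length(u))
    ),
    week3 = condition_profile(
      "week3",
      centroid_trajectory = function(u) 320 + 20 * u,
      bandwidth_trajectory = function(u) rep(55, length(u))
    ),
    week4 = condition_profile(
      "week4",
      centroid_trajectory = function(u) 295 + 25 * u,
      bandwidth_trajectory = function(u) rep(52, length(u))
    ),
    week5 = condition_profile(
      "week5",
      centroid_trajectory = function(u) 285 + 25 * u,
      bandwidth_trajectory = function(u) rep(52, length(u))
    ),
    week6 = condition_profile(
      "week6",
      centroid_trajectory = function(u) 210 + 60 * sin(pi * u),
      bandwidth_trajectory = function(u) rep(45, length(u)),
      transient_gain = 1.5,
      transient_time_ms = 50
    )
  )
}

#' Synthesize one EMG burst
#'
#' Generates amplitude-modulated band-shaped Gaussian noise: white noise is
#' shaped per short overlapped sub-window by a Gaussian band response
#' centered on the profile's centroid trajectory (width = bandwidth
#' trajectory), reassembled by overlap-add, multiplied by the amplitude
#' envelope, and - if the profile requests it - augmented with a
#' Gaussian-windowed wideband pulse (20 ms FWHM) at `transient_time_ms`.
#' The burst duration is drawn from the profile's duration distribution.
#'
#' @param profile a [condition_profile()].
#' @param fs sampling rate in Hz (>= 1000).
#' @param seed integer seed; the burst is reproducible from it.
#' @param duration_ms optional fixed duration override (ms).
#' @return An [emg_burst()] with `group` set to the profile name.
#' @export
generate_burst <- function(profile, fs = 2000, seed = 1L, duration_ms = NULL) {
  if (!is_scalar_num(fs) || fs < 1000)
    stop("fs must be a scalar >= 1000 Hz")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (is.null(duration_ms)) {
    mu <- profile$burst_duration_ms[[1]]
    sd <- profile$burst_duration_ms[[2]]
    duration_ms <- max(180, stats::rnorm(1, mu, sd))
  }
  n <- max(8L, round(duration_ms * fs / 1000))
  # overlap-add band-shaped noise: 20 ms Hann sub-windows, 50% overlap
  L <- 2L * floor(0.020 * fs / 2)
  hop <- L %/% 2L
  w <- hann_periodic(L)
  fgrid <- (0:(L - 1)) * fs / L
  fpos <- pmin(fgrid, fs - fgrid)      # aliased (folded) frequency per FFT bin
  x <- numeric(n + L)
  starts <- seq(1L, n, by = hop)
  for (s in starts) {
    u <- (s - 1 + L / 2) / n                   # normalized time of sub-window center
    u <- min(max(u, 0), 1)
    fc <- profile$centroid_trajectory(u)
    bw <- profile$bandwidth_trajectory(u)
    H <- exp(-((fpos - fc)^2) / (2 * bw^2))
    H[fpos < 30 | fpos > 500] <- 0             # hard band limit of the instrument chain
    z <- stats::fft(stats::rnorm(L))
    seg <- Re(stats::fft(z * H, inverse = TRUE)) / L
    x[s:(s + L - 1L)] <- x[s:(s + L - 1L)] + seg * w
  }
  x <- x[seq_len(n)]
  x <- x / max(stats::sd(x), .Machine$double.eps)   # unit plateau-noise scale
  t_ms <- (seq_len(n) - 1) / fs * 1000
  x <- x * profile$envelope(t_ms, duration_ms)
  if (profile$transient_gain > 0) {
    sigma_ms <- 20 / (2 * sqrt(2 * log(2)))    # 20 ms FWHM
    gwin <- exp(-((t_ms - profile$transient_time_ms)^2) / (2 * sigma_ms^2))
    x <- x + profile$transient_gain * gwin * stats::rnorm(n)
  }
  emg_burst(x, fs, group = profile$name)
}

#' Session specification for the synthetic generator
#'
#' @param profiles named list of [condition_profile()]s (one per condition).
#' @param subjects_per_group integer, synthetic subjects per condition.
#' @param bursts_per_subject integer, bursts per subject session.
#' @param fs sampling rate in Hz.
#' @param baseline_sd_ratio baseline (inter-burst) Gaussian noise SD as a
#'   fraction of the mean burst RMS (default 0.05).
#' @param session_length_s optional fixed session length; by default sized
#'   to fit the requested bursts plus inter-burst gaps with 20% headroom.
#' @param seed integer master seed.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(profiles = default_profiles(),
                         subjects_per_group = 1L,
                         bursts_per_subject = 50L,
                         fs = 2000,
                         baseline_sd_ratio = 0.05,
                         session_length_s = NULL,
                         seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  max_f <- max(vapply(profiles, function(p) {
    u <- seq(0, 1, length.out = 101)
    max(p$centroid_trajectory(u) + p$bandwidth_trajectory(u))
  }, numeric(1)))
  if (fs <= 2 * max_f)
    stop("fs violates the Nyquist margin: need fs > 2 * (max centroid + bandwidth)")
  per_burst_s <- max(vapply(profiles, function(p)
    (p$burst_duration_ms[[1]] + p$inter_burst_interval_ms[[1]]) / 1000, numeric(1)))
  need_s <- bursts_per_subject * per_burst_s * 1.2 + 1
  if (is.null(session_length_s)) session_length_s <- need_s
  if (session_length_s < need_s && bursts_per_subject > 0)
    stop("session_length_s too short for the requested burst count")
  structure(
    list(profiles = profiles, subjects_per_group = as.integer(subjects_per_group),
         bursts_per_subject = as.integer(bursts_per_subject), fs = fs,
         baseline_sd_ratio = baseline_sd_ratio,
         session_length_s = session_length_s, seed = as.integer(seed)),
    class = "session_spec"
  )
}

#' Generate annotated synthetic sessions
#'
#' For each condition and synthetic subject, synthesizes a continuous
#' recording: bursts generated by [generate_burst()] placed at successive
#' onsets separated by inter-burst gaps drawn from the profile's interval
#' distribution, over a floor of low-amplitude Gaussian baseline noise.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [session_spec()].
#' @return list with `recordings` (named list of single-channel
#'   [emg_recording()]s, one per subject) and `annotations` (data.frame
#'   with columns subject, group, burst_id, onset_s, offset_s).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  fs <- spec$fs
  n_sess <- round(spec$session_length_s * fs)
  recordings <- list()
  ann <- list()
  subj_seeds <- split_seed(spec$seed, max(1L, length(spec$profiles) * spec$subjects_per_group))
  k <- 0L
  for (g in seq_along(spec$profiles)) {
    prof <- spec$profiles[[g]]
    for (s in seq_len(spec$subjects_per_group)) {
      k <- k + 1L
      subject <- sprintf("%s_s%02d", prof$name, s)
      seeds <- split_seed(subj_seeds[k], 2L + max(1L, spec$bursts_per_subject))
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      set.seed(seeds[1])
      bursts <- list()
      if (spec$bursts_per_subject > 0) {
        for (b in seq_len(spec$bursts_per_subject))
          bursts[[b]] <- generate_burst(prof, fs, seed = seeds[2L + b])
      }
      burst_rms <- if (length(bursts) > 0)
        mean(vapply(bursts, function(bb) sqrt(mean(bb$samples^2)), numeric(1)))
      else 1
      set.seed(seeds[2])
      x <- stats::rnorm(n_sess, sd = spec$baseline_sd_ratio * burst_rms)
      pos <- round(0.25 * fs)   # first onset at 250 ms
      rows <- list()
      for (b in seq_along(bursts)) {
        nb <- length(bursts[[b]]$samples)
        if (pos + nb > n_sess)
          stop("session length overflow while placing bursts")
        idx <- pos + seq_len(nb)
        x[idx] <- x[idx] + bursts[[b]]$samples
        rows[[b]] <- data.frame(
          subject = subject, group = prof$name, burst_id = b,
          onset_s = pos / fs, offset_s = (pos + nb) / fs,
          stringsAsFactors = FALSE
        )
        gap <- max(0.08, stats::rnorm(1, prof$inter_burst_interval_ms[[1]] / 1000,
                                      prof$inter_burst_interval_ms[[2]] / 1000))
        pos <- pos + nb + round(gap * fs)
      }
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      recordings[[subject]] <- emg_recording(
        x, fs,
        data.frame(subject = subject, group = prof$name,
                   is_noise_channel = FALSE, stringsAsFactors = FALSE)
      )
      ann[[subject]] <- if (length(rows) > 0) do.call(rbind, rows) else NULL
    }
  }
  annotations <- if (length(ann) > 0 && any(!vapply(ann, is.null, logical(1))))
    do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
  else data.frame(subject = character(), group = character(),
                  burst_id = integer(), onset_s = numeric(),
                  offset_s = numeric(), stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  list(recordings = recordings, annotations = annotations)
}
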