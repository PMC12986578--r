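#' STFT spectrogram of a burst
#'
#' Hamming-windowed frames hopped by `window_ms - overlap_ms`; power is the
#' squared STFT modulus, one-sided, normalized so that the per-frame sum
#' over frequency equals the windowed-segment energy. The burst is never
#' zero-padded in time, so frames exist only where fully supported: the
#' first frame center sits at `window_ms/2` from onset and the last at
#' `duration - window_ms/2`. The unsupported edge regions therefore have
#' width `window_ms/2` at each end (40 ms for the default 80 ms window,
#' 15 ms for a 30 ms window). Frames shorter than `nfft` samples are
#' zero-padded in the FFT only.
#'
#' @param burst an [emg_burst()].
#' @param window_ms analysis window length (default 80).
#' @param overlap_ms overlap between successive windows (default 75).
#' @param nfft FFT length in samples (default 160).
#' @return a [tf_map()] with `kind = "stft"`, times relative to burst onset.
#' @export
stft_spectrogram <- function(burst, window_ms = 80, overlap_ms = 75, nfft = 160) {
  stopifnot(inherits(burst, "emg_burst"))
  fs <- burst$fs
  if (overlap_ms >= window_ms) stop("overlap_ms must be < window_ms")
  w_len <- round(window_ms * fs / 1000)
  hop <- max(1L, round((window_ms - overlap_ms) * fs / 1000))
  n <- length(burst$samples)
  if (w_len > n)
    stop("burst shorter than the analysis window; use the 30 ms configuration for short bursts")
  if (nfft < w_len) nfft <- w_len
  win <- hamming_window(w_len)
  starts <- seq(1L, n - w_len + 1L, by = hop)
  frames <- vapply(starts, function(s) {
    seg <- burst$samples[s:(s + w_len - 1L)] * win
    c(seg, numeric(nfft - w_len))
  }, numeric(nfft))
  spec <- Mod(stats::mvfft(frames))^2 / nfft     # nfft x n_frames
  nf <- floor(nfft / 2) + 1L
  spec1 <- spec[1:nf, , drop = FALSE]
  if (nfft %% 2 == 0) spec1[2:(nf - 1L), ] <- 2 * spec1[2:(nf - 1L), ]
  else spec1[2:nf, ] <- 2 * spec1[2:nf, ]
  times <- (starts - 1 + w_len / 2) / fs
  freqs <- (0:(nf - 1L)) * fs / nfft
  tf_map(t(spec1), times_s = times, freqs_hz = freqs, kind = "stft")
}

#' Mean / median frequency trajectory of a time-frequency map
#'
#' Per time column, restricted to mask-valid cells: F_mean is the spectral
#' centroid `sum(f * P) / sum(P)` and F_median the frequency at which the
#' cumulative power reaches half the total, linearly interpolated between
#' bracketing grid bins. Columns with zero total power (or no valid cells)
#' yield `NA`.
#'
#' @param map a [tf_map()].
#' @return data.frame of class `spectral_trajectory` with columns
#'   `times_s`, `f_mean_hz`, `f_median_hz`, `n_valid`.
#' @export
spectral_trajectory <- function(map) {
  stopifnot(inherits(map, "tf_map"))
  nt <- nrow(map$power)
  f <- map$freqs_hz
  fmean <- fmed <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    v <- map$valid[i, ]
    if (!any(v)) next
    p <- map$power[i, ]
    p[!v] <- 0
    tot <- sum(p)
    if (tot <= 0) next
    fmean[i] <- sum(f * p) / tot
    fmed[i] <- interp_median(f, p, tot / 2)
  }
  out <- data.frame(times_s = map$times_s, f_mean_hz = fmean,
                    f_median_hz = fmed,
                    n_valid = as.integer(rowSums(map$valid)))
  class(out) <- c("spectral_trajectory", "data.frame")
  out
}

# Half-power frequency, linearly interpolated between bracketing bins.
# Each bin's mass is treated as centered on its grid frequency, so a
# single-bin spectrum yields exactly that bin's frequency.
interp_median <- function(f, p, target) {
  cumc <- cumsum(p) - p / 2
  i <- which(cumc >= target)[1]
  if (is.na(i)) return(f[length(f)])
  if (i == 1) return(f[1])
  denom <- cumc[i] - cumc[i - 1]
  if (denom <= 0) return(f[i])
  f[i - 1] + (f[i] - f[i - 1]) * (target - cumc[i - 1]) / denom
}

#' Average spectral trajectories across bursts
#'
#' Pointwise mean and standard error over the bursts contributing a
#' non-missing value at each time; times are truncated to the shortest
#' contributing trajectory (bursts are aligned at onset in absolute time).
#'
#' @param trajectories non-empty list of `spectral_trajectory` objects
#'   sharing frame parameters.
#' @param metric `"f_median_hz"` or `"f_mean_hz"`.
#' @return data.frame with `times_s`, `mean`, `sem`, `n_valid`.
#' @export
average_trajectories <- function(trajectories, metric = c("f_median_hz", "f_mean_hz")) {
  metric <- match.arg(metric)
  if (length(trajectories) == 0) stop("empty trajectory list")
  nt <- min(vapply(trajectories, nrow, integer(1)))
  times <- trajectories[[1]]$times_s[seq_len(nt)]
  vals <- vapply(trajectories, function(tr) tr[[metric]][seq_len(nt)],
                 numeric(nt))
  vals <- matrix(vals, nrow = nt)
  n_valid <- rowSums(!is.na(vals))
  m <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_valid > 0, sdv / sqrt(pmax(n_valid, 1)), NA_real_)
  sem[n_valid == 1] <- 0
  m[n_valid == 0] <- NA_real_
  data.frame(times_s = times, mean = m, sem = sem, n_valid = as.integer(n_valid))
}

#' Phase-averaged spectral features of one burst
#'
#' Averages the F_mean / F_median trajectory of a burst within each
#' contraction phase, emitting tidy phase-feature rows.
#'
#' @param burst an [emg_burst()].
#' @param map the burst's [tf_map()].
#' @param partition a [phase_partition()].
#' @param source source tag for the feature table (e.g. `"stft80"`).
#' @return data.frame rows (subject, group, burst_id, phase, source,
#'   metric, value), or `NULL` when the burst is excluded.
#' @export
phase_spectral_features <- function(burst, map, partition = phase_partition(),
                                    source = "stft80") {
  ph <- partition_phases(burst, partition)
  if (ph$excluded) return(NULL)
  tr <- spectral_trajectory(map)
  t_ms <- tr$times_s * 1000
  bounds <- list(
    recruitment = c(-Inf, partition$recruit_end_ms),
    sustained = c(partition$recruit_end_ms, partition$sustain_end_ms + 1e-9),
    derecruitment = c(partition$sustain_end_ms + 1e-9, Inf)
  )
  rows <- list()
  for (phase in names(bounds)) {
    sel <- t_ms >= bounds[[phase]][1] & t_ms < bounds[[phase]][2]
    for (metric in c("f_mean", "f_median")) {
      v <- tr[[paste0(metric, "_hz")]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = burst$subject, group = burst$group, burst_id = burst$burst_id,
        phase = phase, source = source, metric = metric,
        value = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
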