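#' Zero-phase band-pass and notch filtering
#'
#' Applies a 4th-order Butterworth band-pass forward-backward
#' (zero-phase, via [signal::filtfilt()]) followed by a zero-phase IIR
#' notch (biquad, Q = 30) at the power-line frequency. Zero-phase filtering
#' preserves burst onset latencies, which matters for phase-resolved
#' features.
#'
#' @param recording an [emg_recording()].
#' @param low,high band edges in Hz (defaults 30 and 500).
#' @param notch notch center in Hz (default 50); `NULL` or `NA` disables it.
#' @param notch_q notch quality factor (default 30).
#' @return filtered [emg_recording()] of identical length.
#' @export
bandpass_notch <- function(recording, low = 30, high = 500, notch = 50, notch_q = 30) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$fs
  if (!(0 < low && low < high && high < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  use_notch <- !is.null(notch) && !is.na(notch)
  if (use_notch && !(low < notch && notch < high))
    stop("invalid band: notch must lie inside the pass band")
  bp <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  nf <- if (use_notch) design_notch(notch, fs, notch_q)
  out <- recording$samples
  for (j in seq_len(ncol(out))) {
    y <- signal::filtfilt(bp, out[, j])
    if (use_notch) y <- signal::filtfilt(nf$b, nf$a, y)
    out[, j] <- y
  }
  emg_recording(out, fs, recording$channel_meta)
}

# Biquad notch (constrained band-stop), standard audio-EQ design.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Detect EMG bursts with a robust moving-RMS threshold
#'
#' Computes a moving-RMS envelope, thresholds it at
#' `median(envelope) + k_threshold * MAD(envelope)`, drops supra-threshold
#' runs shorter than `min_duration_ms`, merges runs separated by less than
#' `merge_gap_ms`, and refines each onset/offset outward to the nearest
#' crossing of half the threshold. The median/MAD rule makes detection
#' invariant to overall amplitude scaling.
#'
#' @param recording a filtered single- or multi-channel [emg_recording()];
#'   bursts are detected per channel.
#' @param rms_window_ms moving-RMS window (default 10 ms).
#' @param k_threshold MAD multiplier (default 5).
#' @param min_duration_ms minimum burst duration (default 100 ms).
#' @param merge_gap_ms gap below which adjacent runs are merged (default 30 ms).
#' @return list of [emg_burst()] objects with onsets/offsets in seconds.
#' @export
detect_bursts <- function(recording, rms_window_ms = 10, k_threshold = 5,
                          min_duration_ms = 100, merge_gap_ms = 30) {
  stopifnot(inherits(recording, "emg_recording"))
  if (n_samples(recording) == 0) stop("empty recording")
  if (rms_window_ms < 1) stop("rms_window_ms must be >= 1")
  fs <- recording$fs
  out <- list()
  for (j in seq_len(n_channels(recording))) {
    x <- recording$samples[, j]
    meta <- recording$channel_meta[j, ]
    env <- moving_rms(x, round(rms_window_ms * fs / 1000))
    thr <- stats::median(env) + k_threshold * stats::mad(env)
    if (!is.finite(thr) || thr <= 0) next
    runs <- supra_runs(env >= thr)
    if (nrow(runs) == 0) next
    # merge runs separated by short gaps
    merge_gap <- merge_gap_ms * fs / 1000
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (r in 2:nrow(runs)) {
        if (runs$start[r] - merged$end[nrow(merged)] < merge_gap)
          merged$end[nrow(merged)] <- runs$end[r]
        else merged <- rbind(merged, runs[r, ])
      }
    }
    # drop short runs, then refine to the nearest half-threshold crossing
    keep <- (merged$end - merged$start + 1) >= min_duration_ms * fs / 1000
    merged <- merged[keep, , drop = FALSE]
    half <- thr / 2
    bid <- 0L
    for (r in seq_len(nrow(merged))) {
      a <- merged$start[r]
      while (a > 1 && env[a - 1] >= half) a <- a - 1
      b <- merged$end[r]
      while (b < length(env) && env[b + 1] >= half) b <- b + 1
      bid <- bid + 1L
      out[[length(out) + 1L]] <- emg_burst(
        x[a:b], fs, onset_s = (a - 1) / fs, offset_s = b / fs,
        subject = meta$subject, group = meta$group, burst_id = bid
      )
    }
  }
  out
}

supra_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Contraction-phase partition parameters
#'
#' The sustained phase is fixed at 80-150 ms from onset; recruitment is
#' onset to 80 ms and derecruitment 150 ms to offset. Boundary convention:
#' recruitment `[0, recruit_end)`, sustained `[recruit_end, sustain_end]`
#' (closed), derecruitment `(sustain_end, duration]` - the three ranges
#' partition the burst exactly.
#'
#' @param recruit_end_ms recruitment/sustained boundary (default 80).
#' @param sustain_end_ms sustained/derecruitment boundary (default 150).
#' @return object of class `phase_partition`.
#' @export
phase_partition <- function(recruit_end_ms = 80, sustain_end_ms = 150) {
  if (!(0 < recruit_end_ms && recruit_end_ms < sustain_end_ms))
    stop("need 0 < recruit_end_ms < sustain_end_ms")
  structure(list(recruit_end_ms = recruit_end_ms, sustain_end_ms = sustain_end_ms),
            class = "phase_partition")
}

#' Partition a burst into recruitment / sustained / derecruitment ranges
#'
#' Sample index ranges (1-based) for the three contraction phases. A sample
#' at index k sits at time (k-1)/fs from onset. Bursts shorter than the
#' sustained-phase end are flagged as excluded rather than raising an
#' error.
#'
#' @param burst an [emg_burst()].
#' @param partition a [phase_partition()].
#' @return list with `excluded` flag and, when not excluded, integer index
#'   vectors `recruitment`, `sustained`, `derecruitment` forming a disjoint
#'   cover of the burst.
#' @export
partition_phases <- function(burst, partition = phase_partition()) {
  stopifnot(inherits(burst, "emg_burst"), inherits(partition, "phase_partition"))
  n <- length(burst$samples)
  dur_ms <- 1000 * n / burst$fs
  if (dur_ms <= partition$sustain_end_ms)
    return(list(excluded = TRUE, reason = "burst shorter than sustained-phase end"))
  t_ms <- (seq_len(n) - 1) / burst$fs * 1000
  rec <- which(t_ms < partition$recruit_end_ms)
  sus <- which(t_ms >= partition$recruit_end_ms & t_ms <= partition$sustain_end_ms)
  der <- which(t_ms > partition$sustain_end_ms)
  list(excluded = FALSE, recruitment = rec, sustained = sus, derecruitment = der)
}
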