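#' Multichannel EMG recording
#'
#' Container for a continuous multichannel recording: a samples matrix
#' (time in rows, channels in columns), the sampling rate, and per-channel
#' metadata (subject, group, and whether the channel is an auxiliary noise
#' channel appended for noise-assisted decomposition).
#'
#' @param samples numeric matrix, time x channels (a vector is treated as a
#'   single channel).
#' @param fs sampling rate in Hz.
#' @param channel_meta data.frame with one row per channel and columns
#'   `subject` (character), `group` (character) and `is_noise_channel`
#'   (logical). Missing columns are filled with defaults.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_meta = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (time x channels)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  n_ch <- ncol(samples)
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(
      subject = paste0("ch", seq_len(n_ch)),
      group = NA_character_,
      is_noise_channel = FALSE,
      stringsAsFactors = FALSE
    )
  }
  if (nrow(channel_meta) != n_ch)
    stop("`channel_meta` must have one row per channel")
  for (col in c("subject", "group")) {
    if (is.null(channel_meta[[col]])) channel_meta[[col]] <- NA_character_
    channel_meta[[col]] <- as.character(channel_meta[[col]])
  }
  if (is.null(channel_meta$is_noise_channel))
    channel_meta$is_noise_channel <- FALSE
  structure(
    list(samples = samples, fs = fs, channel_meta = channel_meta),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
    ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs
  ))
  cat("  subjects: ", paste(unique(x$channel_meta$subject), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of samples / channels of a recording
#' @param x an `emg_recording`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_channels <- function(x) ncol(x$samples)

#' One detected or annotated muscle contraction
#'
#' @param samples numeric vector of amplitudes for the burst.
#' @param fs sampling rate in Hz.
#' @param onset_s,offset_s burst boundaries in seconds in the parent
#'   recording (half-open interval `[onset_s, offset_s)`).
#' @param subject,group,burst_id provenance fields.
#' @return An object of class `emg_burst`.
#' @export
emg_burst <- function(samples, fs, onset_s = 0, offset_s = onset_s + length(samples) / fs,
                      subject = NA_character_, group = NA_character_, burst_id = NA_integer_) {
  if (length(samples) < 1L) stop("burst must contain at least one sample")
  structure(
    list(samples = as.numeric(samples), fs = fs, onset_s = onset_s,
         offset_s = offset_s, subject = subject, group = group,
         burst_id = burst_id),
    class = "emg_burst"
  )
}

#' @export
print.emg_burst <- function(x, ...) {
  cat(sprintf(
    "<emg_burst> %s/%s #%s: %.1f ms @ %g Hz [%.3f, %.3f) s\n",
    x$subject, x$group, x$burst_id, 1000 * length(x$samples) / x$fs,
    x$fs, x$onset_s, x$offset_s
  ))
  invisible(x)
}

#' Burst duration in milliseconds
#' @param burst an `emg_burst`.
#' @return duration in ms.
#' @export
burst_duration_ms <- function(burst) 1000 * length(burst$samples) / burst$fs

#' Time-frequency map
#'
#' Time x frequency power matrix with its grids and a per-cell validity
#' mask. For STFT maps the mask depends on time only (edge frames are simply
#' not emitted); for CWT maps the mask is the cone of influence and is
#' frequency dependent.
#'
#' @param power numeric matrix, rows = times, columns = frequencies; must be
#'   non-negative.
#' @param times_s strictly increasing frame/translation centers (seconds).
#' @param freqs_hz strictly increasing frequency grid (Hz).
#' @param valid logical matrix of the same shape as `power` (default all
#'   TRUE).
#' @param kind `"stft"` or `"cwt"`.
#' @return An object of class `tf_map`.
#' @export
tf_map <- function(power, times_s, freqs_hz, valid = NULL, kind = c("stft", "cwt")) {
  kind <- match.arg(kind)
  power <- as.matrix(power)
  if (any(power < 0)) stop("power must be non-negative")
  if (length(times_s) != nrow(power) || length(freqs_hz) != ncol(power))
    stop("grid lengths must match power dimensions")
  if (is.unsorted(times_s, strictly = TRUE) || is.unsorted(freqs_hz, strictly = TRUE))
    stop("times and frequencies must be strictly increasing")
  if (is.null(valid)) valid <- matrix(TRUE, nrow(power), ncol(power))
  if (!identical(dim(valid), dim(power))) stop("valid mask shape mismatch")
  structure(
    list(power = power, times_s = as.numeric(times_s),
         freqs_hz = as.numeric(freqs_hz), valid = valid, kind = kind),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf(
    "<tf_map:%s> %d frames x %d freqs; t = [%.1f, %.1f] ms; f = [%.1f, %.1f] Hz; %.0f%% valid\n",
    x$kind, nrow(x$power), ncol(x$power),
    1000 * min(x$times_s), 1000 * max(x$times_s),
    min(x$freqs_hz), max(x$freqs_hz), 100 * mean(x$valid)
  ))
  invisible(x)
}

#' @export
plot.tf_map <- function(x, log_power = TRUE, ...) {
  z <- x$power
  z[!x$valid] <- NA
  if (log_power) z <- log10(z + .Machine$double.eps)
  graphics::image(x$times_s, x$freqs_hz, z,
                  xlab = "time (s)", ylab = "frequency (Hz)", ...)
  invisible(x)
}

#' Intrinsic mode function set
#'
#' Output of multivariate EMD: a (channel, mode, time) array of IMFs plus a
#' per-channel residual. Every channel carries the same number of modes (the
#' multivariate mode-alignment property) and the modes plus the residual sum
#' back to the input channel.
#'
#' @param imfs numeric array with dimensions (channel, mode, time).
#' @param residual numeric matrix (channel x time).
#' @param fs sampling rate in Hz.
#' @param channel_meta as in [emg_recording()].
#' @return An object of class `imf_set`.
#' @export
imf_set <- function(imfs, residual, fs, channel_meta) {
  stopifnot(length(dim(imfs)) == 3L, is.matrix(residual))
  stopifnot(dim(imfs)[1] == nrow(residual), dim(imfs)[3] == ncol(residual))
  structure(
    list(imfs = imfs, residual = residual, fs = fs, channel_meta = channel_meta),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf(
    "<imf_set> %d channel(s) x %d mode(s) x %d samples @ %g Hz (%d noise channel(s))\n",
    dim(x$imfs)[1], dim(x$imfs)[2], dim(x$imfs)[3], x$fs,
    sum(x$channel_meta$is_noise_channel)
  ))
  invisible(x)
}

#' Number of modes in an IMF set
#' @param x an `imf_set`.
#' @return integer mode count (shared by all channels).
#' @export
n_modes <- function(x) dim(x$imfs)[2]

#' Hilbert instantaneous frequency / energy series
#'
#' @param inst_freq_hz array (channel, mode, time) of instantaneous
#'   frequencies in Hz; `NA` where the amplitude is below the validity floor.
#' @param inst_energy array (channel, mode, time) of squared analytic
#'   amplitudes (arbitrary units squared), non-negative.
#' @param fs sampling rate in Hz.
#' @param channel_meta as in [emg_recording()].
#' @return An object of class `hilbert_series`.
#' @export
hilbert_series <- function(inst_freq_hz, inst_energy, fs, channel_meta) {
  stopifnot(identical(dim(inst_freq_hz), dim(inst_energy)))
  if (any(inst_energy < 0)) stop("instantaneous energy must be non-negative")
  structure(
    list(inst_freq_hz = inst_freq_hz, inst_energy = inst_energy, fs = fs,
         channel_meta = channel_meta),
    class = "hilbert_series"
  )
}

#' @export
print.hilbert_series <- function(x, ...) {
  d <- dim(x$inst_freq_hz)
  cat(sprintf(
    "<hilbert_series> %d channel(s) x %d mode(s) x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs
  ))
  invisible(x)
}
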