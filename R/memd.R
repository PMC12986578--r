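#' Noise-assisted multivariate empirical mode decomposition
#'
#' Appends `n_noise_channels` white-Gaussian channels (SD =
#' `noise_sd_ratio` times the mean signal-channel SD) to the recording and
#' runs a single multivariate EMD over the whole channel set. Each sifting
#' iteration projects the multichannel signal onto `n_directions` direction
#' vectors from a Hammersley low-discrepancy sequence mapped to the unit
#' hypersphere, locates the extrema of every projection, interpolates the
#' multivariate signal at those extrema with cubic splines (two mirrored
#' extrema beyond each edge), and subtracts the direction-averaged local
#' mean. A mode is accepted under the three-parameter
#' evaluation of the normalized local mean (thresholds
#' `sift_stop = c(theta1, theta2, alpha)`); decomposition stops when the
#' residual's projections carry fewer than 3 extrema or `max_modes` is
#' reached. Noise channels are retained in the output but flagged in the
#' channel metadata.
#'
#' @param recording an [emg_recording()] (>= 1 signal channel).
#' @param n_noise_channels white-noise channels to append (default 3).
#' @param noise_sd_ratio noise SD as a multiple of the mean signal SD
#'   (default 1.0).
#' @param n_directions projection directions (default 64); raised with a
#'   warning if below twice the total channel count.
#' @param max_modes maximum number of modes (default 10).
#' @param sift_stop numeric `c(theta1, theta2, alpha)` stop thresholds
#'   (default `c(0.05, 0.5, 0.05)`).
#' @param max_sift_iter per-mode sifting cap (default 1000).
#' @param seed integer seed for the noise channels.
#' @return an [imf_set()]; modes plus residual reconstruct every channel.
#' @export
na_memd <- function(recording, n_noise_channels = 3L, noise_sd_ratio = 1.0,
                    n_directions = 64L, max_modes = 10L,
                    sift_stop = c(0.05, 0.5, 0.05), max_sift_iter = 1000L,
                    seed = 1L) {
  stopifnot(inherits(recording, "emg_recording"))
  X <- recording$samples
  if (nrow(X) < 4L) stop("need at least 4 samples to decompose")
  meta <- recording$channel_meta
  if (n_noise_channels >= 1L) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    sd_sig <- mean(apply(X, 2, stats::sd))
    noise <- matrix(stats::rnorm(nrow(X) * n_noise_channels,
                                 sd = noise_sd_ratio * sd_sig),
                    ncol = n_noise_channels)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    X <- cbind(X, noise)
    meta <- rbind(meta, data.frame(
      subject = paste0("noise", seq_len(n_noise_channels)),
      group = NA_character_, is_noise_channel = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  n_ch <- ncol(X)
  if (n_directions < 2L * n_ch) {
    warning("n_directions below twice the channel count; increasing to ", 2L * n_ch)
    n_directions <- 2L * n_ch
  }
  dirs <- hammersley_sphere(n_directions, n_ch)
  modes <- list()
  resid <- X
  for (m in seq_len(max_modes)) {
    if (!memd_decomposable(resid, dirs)) break
    h <- resid
    for (it in seq_len(max_sift_iter)) {
      em <- envelope_mean(h, dirs)
      if (em$n_good == 0L) break
      sx <- sqrt(rowSums(em$mean^2)) / pmax(em$amp, .Machine$double.eps)
      stop_now <- (mean(sx > sift_stop[1]) <= sift_stop[3]) && all(sx <= sift_stop[2])
      h <- h - em$mean
      if (stop_now) break
    }
    modes[[m]] <- h
    resid <- resid - h
  }
  n_modes <- length(modes)
  if (n_modes == 0L) stop("input has no oscillatory content to decompose")
  imfs <- array(0, dim = c(n_ch, n_modes, nrow(X)))
  for (m in seq_len(n_modes)) imfs[, m, ] <- t(modes[[m]])
  imf_set(imfs, t(resid), recording$fs, meta)
}

# Hammersley sequence in [0,1]^d mapped to the unit (d-1)-sphere through
# the Gaussian radial map (inverse-normal transform + normalization).
hammersley_sphere <- function(k, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113)
  if (d - 1 > length(primes)) stop("too many channels for the direction generator")
  u <- matrix(0, nrow = k, ncol = d)
  u[, 1] <- (seq_len(k) - 0.5) / k
  for (j in seq_len(d - 1)) u[, j + 1] <- radical_inverse(seq_len(k), primes[j])
  z <- stats::qnorm(pmin(pmax(u, 1e-9), 1 - 1e-9))
  z / sqrt(rowSums(z^2))
}

radical_inverse <- function(i, base) {
  out <- numeric(length(i))
  f <- 1 / base
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

# TRUE while at least one projection still has >= 3 extrema.
memd_decomposable <- function(X, dirs) {
  memd_has_extrema(X, dirs)
}

local_maxima <- function(p) {
  n <- length(p)
  if (n < 3L) return(integer(0))
  d <- diff(p)
  # collapse exact plateaus by nudging with the previous slope sign
  d[d == 0] <- .Machine$double.eps
  which(d[-length(d)] > 0 & d[-1] < 0) + 1L
}

# Direction-averaged local mean and amplitude for one sifting iteration:
# per direction, project, locate projection maxima/minima, natural cubic
# splines through the multivariate signal at those locations (two mirrored
# extrema beyond each edge), average. Implemented in C++ (memd_core.cpp).
envelope_mean <- function(X, dirs) {
  out <- memd_envelope_mean(X, dirs)
  if (out$n_good == 0L) return(list(mean = NULL, amp = NULL, n_good = 0L))
  list(mean = out$mean / out$n_good, amp = out$amp / out$n_good,
       n_good = out$n_good)
}

#' Hilbert instantaneous frequency and energy of an IMF set
#'
#' Per channel and mode: the analytic signal is computed with the
#' frequency-domain Hilbert multiplier; instantaneous energy is its squared
#' magnitude; instantaneous frequency is the central-difference derivative
#' of the unwrapped phase divided by `2 pi`, median-smoothed over
#' `smooth_ms`, clipped to `[0, fs/2]`, and set missing wherever the
#' analytic amplitude falls below `amp_floor_ratio` times the mode's RMS
#' (near-zero amplitude makes the phase derivative meaningless).
#'
#' @param imfs an [imf_set()].
#' @param smooth_ms median-smoothing window for the frequency (default 5).
#' @param amp_floor_ratio amplitude validity floor relative to mode RMS
#'   (default 0.01).
#' @return a [hilbert_series()].
#' @export
hilbert_if_ie <- function(imfs, smooth_ms = 5, amp_floor_ratio = 0.01) {
  stopifnot(inherits(imfs, "imf_set"))
  d <- dim(imfs$imfs)
  fs <- imfs$fs
  inst_f <- array(NA_real_, d)
  inst_e <- array(0, d)
  k <- round(smooth_ms * fs / 1000)
  if (k %% 2 == 0) k <- k + 1L
  for (ch in seq_len(d[1])) {
    for (m in seq_len(d[2])) {
      x <- imfs$imfs[ch, m, ]
      rms <- sqrt(mean(x^2))
      if (rms == 0) next
      z <- analytic_signal(x)
      a <- Mod(z)
      inst_e[ch, m, ] <- a^2
      phase <- unwrap_phase(Arg(z))
      f <- central_diff(phase) * fs / (2 * pi)
      if (k >= 3 && length(f) > k) f <- stats::runmed(f, k, endrule = "median")
      f <- pmin(pmax(f, 0), fs / 2)
      f[a < amp_floor_ratio * rms] <- NA_real_
      inst_f[ch, m, ] <- f
    }
  }
  hilbert_series(inst_f, inst_e, fs, imfs$channel_meta)
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

#' Per-mode marginal spectra and dominant-frequency ranges
#'
#' Welch power spectrum of each mode, averaged over the signal (non-noise)
#' channels; the dominant range of a mode is the span of frequencies whose
#' averaged power is at least half the mode's spectral peak.
#'
#' @param imfs an [imf_set()].
#' @param seg_len Welch segment length in samples (default 512).
#' @return list with `freq`, `psd` (mode x frequency matrix) and
#'   `dominant` (data.frame mode, f_lo_hz, f_hi_hz, f_peak_hz).
#' @export
imf_marginal_spectra <- function(imfs, seg_len = 512L) {
  stopifnot(inherits(imfs, "imf_set"))
  sig <- which(!imfs$channel_meta$is_noise_channel)
  if (length(sig) == 0) sig <- seq_len(dim(imfs$imfs)[1])
  nm <- n_modes(imfs)
  psd <- NULL
  freq <- NULL
  for (m in seq_len(nm)) {
    acc <- NULL
    for (ch in sig) {
      w <- welch_psd(imfs$imfs[ch, m, ], imfs$fs, seg_len)
      if (is.null(acc)) { acc <- w$psd; freq <- w$freq } else acc <- acc + w$psd
    }
    acc <- acc / length(sig)
    if (is.null(psd)) psd <- matrix(0, nm, length(acc))
    psd[m, ] <- acc
  }
  dominant <- do.call(rbind, lapply(seq_len(nm), function(m) {
    p <- psd[m, ]
    above <- which(p >= max(p) / 2)
    data.frame(mode = m, f_lo_hz = freq[min(above)], f_hi_hz = freq[max(above)],
               f_peak_hz = freq[which.max(p)])
  }))
  list(freq = freq, psd = psd, dominant = dominant)
}

#' Phase-resolved IMF features per burst
#'
#' Slices the Hilbert series of each subject channel at the annotated burst
#' boundaries and computes, per burst, mode and contraction phase, the mean
#' instantaneous frequency (over non-missing samples) and the mean
#' instantaneous energy, emitting tidy phase-feature rows with source tags
#' `imf<k>`.
#'
#' @param hs a [hilbert_series()] from [hilbert_if_ie()].
#' @param annotations burst annotation data.frame (subject, group,
#'   burst_id, onset_s, offset_s); subjects must match channel metadata.
#' @param partition a [phase_partition()].
#' @param modes integer vector of mode indices to report (default 2:4).
#' @return phase-feature data.frame; annotations outside the decomposed
#'   record, or bursts shorter than the sustained-phase end, are skipped.
#' @export
segment_imfs <- function(hs, annotations, partition = phase_partition(),
                         modes = 2:4) {
  stopifnot(inherits(hs, "hilbert_series"))
  d <- dim(hs$inst_freq_hz)
  fs <- hs$fs
  modes <- modes[modes <= d[2]]
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    ch <- which(hs$channel_meta$subject == ann$subject &
                  !hs$channel_meta$is_noise_channel)
    if (length(ch) != 1L) next
    a <- round(ann$onset_s * fs) + 1L
    b <- round(ann$offset_s * fs)
    if (a < 1L || b > d[3] || b <= a) next
    nb <- b - a + 1L
    fake <- emg_burst(numeric(nb), fs)
    ph <- partition_phases(fake, partition)
    if (ph$excluded) next
    for (m in modes) {
      f_series <- hs$inst_freq_hz[ch, m, a:b]
      e_series <- hs$inst_energy[ch, m, a:b]
      for (phase in c("recruitment", "sustained", "derecruitment")) {
        sel <- ph[[phase]]
        fv <- f_series[sel]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = ann$subject, group = ann$group, burst_id = ann$burst_id,
          phase = phase, source = paste0("imf", m),
          metric = c("inst_freq_mean", "inst_energy_mean"),
          value = c(if (any(!is.na(fv))) mean(fv, na.rm = TRUE) else NA_real_,
                    mean(e_series[sel])),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(subject = character(), group = character(),
                      burst_id = integer(), phase = character(),
                      source = character(), metric = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
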