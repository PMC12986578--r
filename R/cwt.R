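#' Bump mother wavelet
#'
#' Analytic wavelet defined in the frequency domain as
#' `psi_hat(xi) = exp(1 - 1/(1 - ((xi - mu)/sigma)^2))` on the support
#' `|xi - mu| < sigma` and zero elsewhere (in particular zero for all
#' non-positive frequencies, so the transform is analytic). `mu` is the
#' dimensionless center of the bump and `sigma` its half-width; the peak
#' response of scale `s` falls at frequency `f = mu / (2 pi s)`.
#'
#' @param mu bump center (default 5).
#' @param sigma bump half-width (default 0.6); requires `0 < sigma < mu`.
#' @return object of class `bump_wavelet`.
#' @export
bump_wavelet <- function(mu = 5, sigma = 0.6) {
  if (!(0 < sigma && sigma < mu))
    stop("need 0 < sigma < mu for an analytic Bump wavelet")
  structure(list(mu = mu, sigma = sigma), class = "bump_wavelet")
}

# Frequency-domain bump response at angular frequencies xi.
bump_hat <- function(xi, wavelet) {
  z <- (xi - wavelet$mu) / wavelet$sigma
  out <- numeric(length(xi))
  ok <- abs(z) < 1 & xi > 0
  out[ok] <- exp(1 - 1 / (1 - z[ok]^2))
  out
}

# Two-sided e-folding half-width (in scale-1 time units) of the mother
# wavelet's time-domain envelope, obtained numerically by inverse FFT of
# psi_hat on a dense grid. Cached per (mu, sigma).
.bump_cache <- new.env(parent = emptyenv())

bump_efolding_time <- function(wavelet) {
  key <- sprintf("mu%.6g_sigma%.6g", wavelet$mu, wavelet$sigma)
  if (!is.null(.bump_cache[[key]])) return(.bump_cache[[key]])
  n <- 2^16
  dt <- 2 * pi / (wavelet$mu + wavelet$sigma) / 64   # fine sampling of the carrier
  omega <- 2 * pi * (0:(n - 1)) / (n * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt
  psi <- stats::fft(bump_hat(omega, wavelet), inverse = TRUE) / (n * dt)
  env <- Mod(psi)
  t <- (0:(n - 1)) * dt
  t[t > n * dt / 2] <- t[t > n * dt / 2] - n * dt
  peak <- max(env)
  tau_e <- max(abs(t[env >= peak / exp(1)]))
  .bump_cache[[key]] <- tau_e
  tau_e
}

#' Continuous wavelet transform of a burst with the Bump wavelet
#'
#' Frequency-domain implementation on a geometric frequency grid with
#' `voices_per_octave` voices spanning `[fmin_hz, fmax_hz]` via the
#' peak-frequency convention `f = mu / (2 pi s)`. The signal is
#' zero-extended (no reflection) before the FFT so that edge effects remain
#' exactly what the cone of influence masks. Power is `|W|^2 / s` and the
#' validity mask is the cone of influence computed from the wavelet's
#' numerically determined e-folding time envelope half-width.
#'
#' @param burst an [emg_burst()].
#' @param wavelet a [bump_wavelet()].
#' @param fmin_hz,fmax_hz frequency band (defaults 30 and 500); must
#'   satisfy `fmin < fmax <= fs/2`.
#' @param voices_per_octave scale-grid density (default 16).
#' @return a [tf_map()] with `kind = "cwt"`, one time per input sample.
#' @export
bump_cwt <- function(burst, wavelet = bump_wavelet(), fmin_hz = 30,
                     fmax_hz = 500, voices_per_octave = 16) {
  stopifnot(inherits(burst, "emg_burst"))
  fs <- burst$fs
  if (!(0 < fmin_hz && fmin_hz < fmax_hz && fmax_hz <= fs / 2))
    stop("invalid band: need 0 < fmin < fmax <= fs/2")
  x <- burst$samples
  n <- length(x)
  npad <- next_pow2(2L * n)
  xhat <- stats::fft(c(x, numeric(npad - n)))
  n_oct <- log2(fmax_hz / fmin_hz)
  expo <- seq(0, n_oct, by = 1 / voices_per_octave)
  if (max(expo) < n_oct) expo <- c(expo, n_oct)   # keep fmax on the grid
  freqs <- fmin_hz * 2^expo
  scales <- wavelet$mu / (2 * pi * freqs)
  omega <- 2 * pi * (0:(npad - 1)) * fs / npad    # rad/s, positive branch only matters
  omega[omega > pi * fs] <- 0                     # negative frequencies: psi_hat = 0 anyway
  power <- matrix(0, nrow = n, ncol = length(freqs))
  for (j in seq_along(freqs)) {
    psih <- bump_hat(scales[j] * omega, wavelet)
    w <- stats::fft(xhat * Conj(psih), inverse = TRUE) / npad
    power[, j] <- Mod(w[seq_len(n)])^2 / scales[j]
  }
  map <- tf_map(power, times_s = (seq_len(n) - 1) / fs, freqs_hz = freqs,
                kind = "cwt")
  map$valid <- cone_of_influence(map, wavelet)
  map
}

#' Cone of influence of a CWT map
#'
#' For each scale `s`, cells within `t_e(s) = s * tau_e` of either burst
#' edge are marked invalid, where `tau_e` is the two-sided e-folding
#' half-width of the mother wavelet's time envelope (computed once
#' numerically and cached). Larger scales (lower frequencies) are excluded
#' over proportionally wider edge bands; a scale whose burst is shorter
#' than `2 t_e(s)` is fully masked.
#'
#' @param map a [tf_map()] with `kind = "cwt"`.
#' @param wavelet the [bump_wavelet()] used to compute the map.
#' @return logical validity matrix, same shape as `map$power`.
#' @export
cone_of_influence <- function(map, wavelet = bump_wavelet()) {
  stopifnot(inherits(map, "tf_map"))
  if (map$kind != "cwt") stop("cone of influence applies to CWT maps only")
  tau_e <- bump_efolding_time(wavelet)
  scales <- wavelet$mu / (2 * pi * map$freqs_hz)
  t0 <- min(map$times_s)
  t1 <- max(map$times_s)
  valid <- matrix(FALSE, nrow = nrow(map$power), ncol = ncol(map$power))
  for (j in seq_along(scales)) {
    te <- scales[j] * tau_e
    valid[, j] <- (map$times_s - t0 >= te) & (t1 - map$times_s >= te)
  }
  valid
}
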