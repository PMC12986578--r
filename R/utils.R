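# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Periodic Hann window (sums to a constant under 50% overlap-add).
hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Symmetric Hamming window, the spectrogram frame taper.
hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Analytic signal via the frequency-domain Hilbert multiplier.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Welch power spectral density: averaged modified periodograms over
# 50%-overlapped Hann segments. Returns one-sided density on a uniform grid.
welch_psd <- function(x, fs, seg_len = min(length(x), 512L)) {
  seg_len <- min(seg_len, length(x))
  hop <- max(1L, floor(seg_len / 2))
  w <- hann_periodic(seg_len)
  u <- sum(w^2)
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    p <- p[1:nf]
    if (seg_len %% 2 == 0) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1L)) * fs / seg_len, psd = acc / length(starts))
}

# Spectral centroid of a one-sided PSD restricted to a band.
psd_centroid <- function(freq, psd, band = c(-Inf, Inf)) {
  keep <- freq >= band[1] & freq <= band[2]
  sum(freq[keep] * psd[keep]) / sum(psd[keep])
}

# Moving RMS with a centered rectangular window.
moving_rms <- function(x, n) {
  n <- max(1L, as.integer(n))
  ms <- stats::filter(x^2, rep(1 / n, n), sides = 2)
  ms <- as.numeric(ms)
  # fill edges (partial windows) with the nearest full-window value
  first <- which(!is.na(ms))[1]
  last <- tail(which(!is.na(ms)), 1)
  ms[seq_len(first - 1)] <- ms[first]
  if (last < length(ms)) ms[(last + 1):length(ms)] <- ms[last]
  sqrt(pmax(ms, 0))
}

# Deterministic child seeds for pipeline stages: one global seed fans out
# through a single draw of stage seeds (documented splitting rule).
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
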