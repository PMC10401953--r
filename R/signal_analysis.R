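#' Lag autocorrelation table
#'
#' Lag-N autocorrelation measures a signal's correlation with a copy of
#' itself delayed by N samples. This uses the per-lag Pearson definition
#' (`cor(x[1:(n-N)], x[(1+N):n])`), not the biased FFT estimator, so each
#' lag's value is an ordinary correlation coefficient. Missing samples are
#' dropped pairwise.
#'
#' @param rec an `fp_recording`.
#' @param channel channel name.
#' @param max_lag largest lag in samples (`1 <= max_lag < n`).
#' @return data.frame with columns `lag` (samples), `lag_s` (seconds), `r`,
#'   and `ci` (the white-noise 95% band half-width `1.96 / sqrt(n)`).
#' @export
autocorrelation <- function(rec, channel, max_lag) {
  x <- get_channel(rec, channel)
  n <- length(x)
  if (max_lag < 1L || max_lag >= n)
    stop("`max_lag` must be in [1, n - 1] samples")
  if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
    stop("channel '", channel, "' has zero variance")
  r <- vapply(0:max_lag, function(k) {
    if (k == 0L) return(1)
    stats::cor(x[1:(n - k)], x[(1 + k):n], use = "complete.obs")
  }, numeric(1))
  data.frame(lag = 0:max_lag, lag_s = (0:max_lag) / rec$rate, r = r,
             ci = 1.96 / sqrt(n))
}

# Hann-windowed short-time power frames shared by power_spectrum/spectrogram.
# Returns one-sided power columns scaled so that sum(power) * df equals the
# mean-removed variance of a stationary input (discrete Parseval).
stft_power <- function(x, rate, seg_len, starts) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / seg_len)  # Hann
  wnorm <- sum(w^2)
  nfreq <- seg_len %/% 2 + 1L
  p <- vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (wnorm * rate)
    one <- sp[seq_len(nfreq)]
    # fold negative frequencies into positive (except DC / Nyquist)
    inner <- 2:(nfreq - if (seg_len %% 2L == 0L) 1L else 0L)
    one[inner] <- 2 * one[inner]
    one
  }, numeric(nfreq))
  list(freq = (seq_len(nfreq) - 1L) * rate / seg_len,
       power = matrix(p, nrow = nfreq))
}

#' Averaged-periodogram power spectral density
#'
#' Welch's method: the channel is cut into Hann-windowed, mean-removed,
#' overlapping segments whose periodograms are averaged. Power is scaled so
#' that the integral of the spectrum over frequency approximates the signal
#' variance.
#'
#' @param rec an `fp_recording`.
#' @param channel channel name.
#' @param segment_len segment length in samples (>= 8; default
#'   `min(n, 256 * ceiling(rate))` capped at `n`).
#' @param overlap fractional overlap between segments in `[0, 1)`.
#' @return data.frame with columns `frequency` (Hz, 0 to rate/2) and `power`.
#' @export
power_spectrum <- function(rec, channel, segment_len = NULL, overlap = 0.5) {
  x <- get_channel(rec, channel)
  n <- length(x)
  if (is.null(segment_len)) segment_len <- min(n, 256L * ceiling(rec$rate))
  segment_len <- as.integer(segment_len)
  if (segment_len < 8L) stop("`segment_len` must be >= 8 samples")
  if (segment_len > n) stop("`segment_len` exceeds the channel length")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  hop <- max(1L, as.integer(round(segment_len * (1 - overlap))))
  starts <- seq(1L, n - segment_len + 1L, by = hop)
  st <- stft_power(x, rec$rate, segment_len, starts)
  data.frame(frequency = st$freq, power = rowMeans(st$power))
}

#' Spectrogram (short-time power over time)
#'
#' @param rec an `fp_recording`.
#' @param channel channel name.
#' @param window_len window length in samples.
#' @param hop hop between window starts in samples (>= 1).
#' @return list with `time` (window centers, seconds), `frequency` (Hz) and
#'   `power` (frequency x time matrix).
#' @export
spectrogram <- function(rec, channel, window_len, hop) {
  x <- get_channel(rec, channel)
  n <- length(x)
  window_len <- as.integer(window_len)
  if (window_len < 8L) stop("`window_len` must be >= 8 samples")
  if (window_len > n) stop("`window_len` exceeds the channel length")
  if (hop < 1L) stop("`hop` must be >= 1")
  starts <- seq(1L, n - window_len + 1L, by = as.integer(hop))
  st <- stft_power(x, rec$rate, window_len, starts)
  centers <- time_axis(rec)[starts] + (window_len - 1L) / (2 * rec$rate)
  list(time = centers, frequency = st$freq, power = st$power)
}
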