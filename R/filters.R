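#' Zero-phase Chebyshev type-II band-pass filter
#'
#' Designs a 4th-order Chebyshev type-II band-pass and applies it
#' forward-backward (`signal::filtfilt`), so the net filter has zero phase
#' and peak positions are preserved for the peak-matching alignment.
#' The Chebyshev type-II prototype is specified by its stopband; to realize
#' a stated passband of `low_hz`-`high_hz` the stopband edges are placed
#' outside it at `stop_margin[1] * low_hz` and `stop_margin[2] * high_hz`
#' with `atten_db` (default 40 dB) attenuation.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Passband edges, `0 < low < high < fs/2`.
#' @param order Filter order of the prototype (default 4).
#' @param atten_db Stopband attenuation in dB.
#' @param stop_margin Multipliers placing the stopband edges relative to the
#'   passband edges.
#' @return Filtered signal, same length as `x`.
#' @export
cheby2_bandpass <- function(x, fs, low_hz, high_hz, order = 4,
                            atten_db = 40, stop_margin = c(0.4, 1.8)) {
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2)) {
    stop("need 0 < low_hz < high_hz < fs/2")
  }
  if (length(x) <= 6 * order) stop("signal too short to filter (need > ", 6 * order, " samples)")
  ws <- c(low_hz * stop_margin[1], high_hz * stop_margin[2]) / (fs / 2)
  if (ws[2] >= 1) ws[2] <- 0.999
  flt <- signal::cheby2(order, atten_db, ws, type = "pass")
  as.numeric(signal::filtfilt(flt, as.numeric(x)))
}

#' Band-pass an ECG trace (0.5-20 Hz)
#' @inheritParams cheby2_bandpass
#' @return Filtered signal.
#' @export
filter_ecg <- function(x, fs) cheby2_bandpass(x, fs, 0.5, 20)

#' Band-pass a PPG trace (0.5-10 Hz)
#' @inheritParams cheby2_bandpass
#' @return Filtered signal.
#' @export
filter_ppg <- function(x, fs) cheby2_bandpass(x, fs, 0.5, 10)

# Centered moving average with window w (samples); edges use partial windows
# so the output keeps the input length and scale.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
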