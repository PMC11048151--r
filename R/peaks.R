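#' Detect R peaks with the Pan-Tompkins method
#'
#' Classic QRS detection chain: 5-15 Hz band-pass (zero-phase), derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual-threshold
#' peak classification with search-back and a 200 ms refractory period.
#' Each accepted detection is refined to the local maximum of the
#' band-passed ECG so reported indices sit on the R wave itself.
#'
#' @param ecg Numeric ECG trace (raw or band-passed).
#' @param fs Sampling rate in Hz (>= 100).
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (possibly empty).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (fs < 100) stop("fs must be >= 100 Hz for QRS detection")
  n <- length(ecg)
  if (n < 2 * fs) stop("need at least 2 s of signal")
  if (all(ecg == ecg[1])) return(integer(0))

  bp <- as.numeric(signal::filtfilt(
    signal::butter(2, c(5, 15) / (fs / 2), type = "pass"), as.numeric(ecg)))
  der <- c(0, diff(bp))
  sq <- der^2
  integ <- moving_average(sq, round(0.15 * fs))

  # candidate peaks of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand)) return(integer(0))

  refractory <- round(0.2 * fs)
  init <- integ[seq_len(min(n, 2 * fs))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  if (spki <= 0) return(integer(0))

  peaks <- integer(0)
  rr <- numeric(0)
  pending <- integer(0)  # candidates since last accepted QRS (for search-back)
  for (p in cand) {
    v <- integ[p]
    thr1 <- npki + 0.25 * (spki - npki)
    last <- if (length(peaks)) peaks[length(peaks)] else -Inf
    if (v > thr1 && (p - last) > refractory) {
      peaks <- c(peaks, p)
      spki <- 0.125 * v + 0.875 * spki
      if (length(peaks) >= 2L) {
        rr <- c(rr, diff(utils::tail(peaks, 2L)))
        if (length(rr) > 8L) rr <- utils::tail(rr, 8L)
      }
      pending <- integer(0)
    } else {
      npki <- 0.125 * v + 0.875 * npki
      pending <- c(pending, p)
      # search-back: if a beat seems overdue, accept the best pending
      # candidate that clears the lower threshold
      if (length(rr) >= 2L && length(peaks) &&
          (p - peaks[length(peaks)]) > 1.66 * mean(rr)) {
        ok <- pending[integ[pending] > 0.5 * thr1 &
                        (pending - peaks[length(peaks)]) > refractory]
        if (length(ok)) {
          pb <- ok[which.max(integ[ok])]
          peaks <- sort(c(peaks, pb))
          spki <- 0.25 * integ[pb] + 0.75 * spki
          pending <- pending[pending > pb]
        }
      }
    }
  }
  if (!length(peaks)) return(integer(0))

  # refine to the band-passed ECG maximum near each detection
  w <- as.integer(round(0.1 * fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p) - w); hi <- min(n, as.integer(p) + w)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  enforce_min_separation(refined, bp, refractory)
}

#' Detect PPG systolic peaks with the two-moving-averages block method
#'
#' Block-based systolic detection: 0.5-8 Hz band-pass (zero-phase), clip
#' negative values, square, then compare a 111 ms "peak" moving average
#' against a 667 ms "beat" moving average plus an offset of 2% of the mean
#' squared amplitude.  Runs where the peak average wins and that last at
#' least 111 ms become blocks of interest; each block contributes the
#' band-passed signal's argmax as one systolic peak.  A 300 ms minimum
#' separation removes double counts.
#'
#' @param ppg Numeric PPG trace.
#' @param fs Sampling rate in Hz (>= 100).
#' @return Strictly increasing integer vector of systolic-peak indices
#'   (possibly empty).
#' @export
detect_systolic_peaks <- function(ppg, fs) {
  if (fs < 100) stop("fs must be >= 100 Hz for systolic detection")
  n <- length(ppg)
  if (n < 2 * fs) stop("need at least 2 s of signal")
  if (all(ppg == ppg[1])) return(integer(0))

  bp <- as.numeric(signal::filtfilt(
    signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass"), as.numeric(ppg)))
  sq <- pmax(bp, 0)^2
  w1 <- round(0.111 * fs)
  w2 <- round(0.667 * fs)
  ma_peak <- moving_average(sq, w1)
  ma_beat <- moving_average(sq, w2)
  thr <- ma_beat + 0.02 * mean(sq)

  above <- ma_peak > thr
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w1
  if (!any(keep)) return(integer(0))
  peaks <- mapply(function(s, e) s + which.max(bp[s:e]) - 1L,
                  starts[keep], ends[keep])
  enforce_min_separation(sort(unique(as.integer(peaks))), bp, round(0.3 * fs))
}

# Drop peaks closer than min_sep, keeping the larger-amplitude one.
enforce_min_separation <- function(peaks, amp, min_sep) {
  if (length(peaks) < 2L) return(peaks)
  out <- peaks[1L]
  for (p in peaks[-1L]) {
    last <- out[length(out)]
    if (p - last > min_sep) {
      out <- c(out, p)
    } else if (amp[p] > amp[last]) {
      out[length(out)] <- p
    }
  }
  out
}
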