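#' Remove the ECG-PPG pulse-arrival lag (Alignment I)
#'
#' The PPG trails the ECG by the pulse arrival time.  Following the
#' third-systolic-peak convention, the lag is taken as the distance from the
#' R peak nearest at-or-before the third systolic peak to that systolic
#' peak; the PPG is advanced by this many samples and both channels are
#' truncated to the common overlap (so the aligned record is shorter than
#' the original).
#'
#' @param record A [new_record()] object.
#' @param r_peaks,sys_peaks Optional precomputed peak indices; when `NULL`
#'   they are detected with [detect_r_peaks()] / [detect_systolic_peaks()]
#'   on the band-passed channels.
#' @return A list of class `aligned_record`: `ecg`, `ppg` (equal length),
#'   `lag_samples`, `fs`, `record_id`.
#' @export
align_pair <- function(record, r_peaks = NULL, sys_peaks = NULL) {
  stopifnot(inherits(record, "cardio_record"))
  if (is.null(r_peaks)) {
    r_peaks <- detect_r_peaks(filter_ecg(record$ecg, record$fs), record$fs)
  }
  if (is.null(sys_peaks)) {
    sys_peaks <- detect_systolic_peaks(filter_ppg(record$ppg, record$fs), record$fs)
  }
  if (length(sys_peaks) < 3L) {
    stop("alignment needs at least 3 systolic peaks (got ", length(sys_peaks), ")")
  }
  s3 <- sys_peaks[3L]
  prior <- r_peaks[r_peaks <= s3]
  if (!length(prior)) {
    stop("no R peak found at or before the third systolic peak; cannot align")
  }
  lag <- as.integer(s3 - max(prior))
  n <- length(record$ecg)
  structure(
    list(ecg = record$ecg[seq_len(n - lag)],
         ppg = record$ppg[seq.int(1L + lag, n)],
         lag_samples = lag, fs = record$fs, record_id = record$record_id),
    class = "aligned_record"
  )
}

#' @export
print.aligned_record <- function(x, ...) {
  cat(sprintf("<aligned_record '%s'>  %d samples @ %g Hz, PPG advanced %d samples\n",
              x$record_id, length(x$ecg), x$fs, x$lag_samples))
  invisible(x)
}

#' Min-max normalization to a target range
#'
#' Affine map sending the signal minimum to `range[1]` and the maximum to
#' `range[2]`.  Constant signals have no dynamic range and are rejected.
#'
#' @param x Numeric signal.
#' @param range Length-2 target range (default `c(0, 1)`).
#' @return Rescaled signal.
#' @export
normalize_minmax <- function(x, range = c(0, 1)) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("cannot min-max normalize a constant signal")
  range[1] + (x - lo) * (range[2] - range[1]) / (hi - lo)
}

#' Cut an aligned record into consecutive fixed-length segments
#'
#' Keeps the first `record_seconds_used` seconds (default 294) and divides
#' them into consecutive non-overlapping `segment_seconds`-long windows
#' (375 samples at the defaults), in temporal order.
#'
#' @param aligned An [align_pair()] result (or any list with `ecg`, `ppg`,
#'   `fs`, `record_id`).
#' @param cfg A [default_config()] list.
#' @return A list of class `segment_set`: `ppg` and `ecg` are
#'   `seg_len x n_segments` matrices (column = segment), `mask` a logical
#'   matrix of the same shape (`TRUE` = ECG sample present), plus `fs`,
#'   `seg_len`, `record_id`, `gap` (NULL until [inject_gap()]).
#' @export
segment_record <- function(aligned, cfg = default_config()) {
  seg_len <- segment_samples(cfg)
  total <- as.integer(round(cfg$record_seconds_used * cfg$fs))
  if (total %% seg_len != 0L) {
    stop("record_seconds_used must be a whole number of segments")
  }
  if (length(aligned$ecg) < total) {
    stop("aligned record too short: ", length(aligned$ecg), " < ", total, " samples")
  }
  idx <- seq_len(total)
  structure(
    list(ppg = matrix(aligned$ppg[idx], nrow = seg_len),
         ecg = matrix(aligned$ecg[idx], nrow = seg_len),
         mask = matrix(TRUE, nrow = seg_len, ncol = total %/% seg_len),
         fs = cfg$fs, seg_len = seg_len,
         record_id = aligned$record_id, gap = NULL),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set '%s'>  %d segments x %d samples @ %g Hz%s\n",
              x$record_id, ncol(x$ecg), x$seg_len, x$fs,
              if (is.null(x$gap)) ""
              else sprintf(", gap %gs @ sample %d", x$gap$gap_seconds,
                           x$gap$start_sample)))
  invisible(x)
}

#' Contiguous temporal train/validation/test split
#'
#' The first 60% of segments form the training set, the next 20% the
#' validation set, and the remainder the test set (fractions from `cfg`;
#' boundaries via `floor` of the cumulative fractions).
#'
#' @param n_segments Number of segments (or a `segment_set`).
#' @param cfg A [default_config()] list.
#' @return List with integer index vectors `train`, `val`, `test`; the
#'   union covers `1:n_segments` and the parts are disjoint and contiguous.
#' @export
split_segments <- function(n_segments, cfg = default_config()) {
  if (inherits(n_segments, "segment_set")) n_segments <- ncol(n_segments$ecg)
  n <- as.integer(n_segments)
  if (n < 5L) stop("need at least 5 segments to split (got ", n, ")")
  f <- cfg$split_fractions
  a <- floor(f[["train"]] * n)
  b <- floor((f[["train"]] + f[["val"]]) * n)
  list(train = seq_len(a),
       val = seq.int(a + 1L, b),
       test = seq.int(b + 1L, n))
}

#' Inject one contiguous missing-ECG gap into the training portion
#'
#' Blanks `gap_seconds` of ECG (set to 0, mask `FALSE`) at a position drawn
#' uniformly (seeded) within the training portion of the record; the gap may
#' cross segment boundaries.  The PPG is untouched, and validation/test
#' reference ECG stays intact so evaluation is well defined.
#'
#' @param segments A [segment_record()] result.
#' @param gap_seconds Gap length in seconds (1-4 in the reference setup).
#' @param seed Integer seed for the gap position.
#' @param split A [split_segments()] result for this set (defaults to the
#'   configured split of all segments).
#' @param cfg A [default_config()] list.
#' @return The `segment_set` with blanked ECG samples, updated `mask`, and
#'   `gap = list(gap_seconds, start_sample, record_id)` (start in 1-based
#'   record coordinates).
#' @export
inject_gap <- function(segments, gap_seconds, seed = 1L, split = NULL,
                       cfg = default_config()) {
  stopifnot(inherits(segments, "segment_set"))
  if (is.null(split)) split <- split_segments(ncol(segments$ecg), cfg)
  gap_len <- as.integer(round(gap_seconds * segments$fs))
  train_len <- length(split$train) * segments$seg_len
  if (gap_len > train_len) {
    stop("gap (", gap_len, " samples) exceeds the training portion (",
         train_len, " samples)")
  }
  start <- withr::with_seed(
    seed, sample.int(train_len - gap_len + 1L, 1L))
  flat <- start:(start + gap_len - 1L)        # record coordinates
  seg <- (flat - 1L) %/% segments$seg_len + 1L
  row <- (flat - 1L) %% segments$seg_len + 1L
  segments$ecg[cbind(row, seg)] <- 0
  segments$mask[cbind(row, seg)] <- FALSE
  segments$gap <- list(gap_seconds = gap_seconds, start_sample = start,
                       record_id = segments$record_id)
  segments
}

#' Run the full preprocessing chain on one record
#'
#' Filtering (Chebyshev type-II band-pass, 0.5-20 Hz ECG / 0.5-10 Hz PPG),
#' peak detection, Alignment I, per-record min-max normalization of both
#' channels to `[0, 1]`, truncation to `record_seconds_used`, and
#' segmentation.  Gap injection is a separate, experiment-level step
#' ([inject_gap()]).
#'
#' @param record A [new_record()] object.
#' @param cfg A [default_config()] list.
#' @return A `segment_set` (see [segment_record()]) with an extra
#'   `lag_samples` element recording the Alignment I advance.
#' @export
preprocess_record <- function(record, cfg = default_config()) {
  stopifnot(inherits(record, "cardio_record"))
  ecg_f <- filter_ecg(record$ecg, record$fs)
  ppg_f <- filter_ppg(record$ppg, record$fs)
  filtered <- new_record(ecg_f, ppg_f, fs = record$fs,
                         record_id = record$record_id)
  aligned <- align_pair(filtered)
  aligned$ecg <- normalize_minmax(aligned$ecg)
  aligned$ppg <- normalize_minmax(aligned$ppg)
  out <- segment_record(aligned, cfg)
  out$lag_samples <- aligned$lag_samples
  out
}
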