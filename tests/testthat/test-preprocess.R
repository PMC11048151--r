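test_that("band-pass filter is linear, selective, and zero-phase", {
  fs <- 125
  n <- 30 * fs
  t0 <- (0:(n - 1)) / fs
  expect_equal(cheby2_bandpass(rep(0, n), fs, 0.5, 10), rep(0, n))
  ratio <- function(f, low, high) {
    y <- cheby2_bandpass(sin(2 * pi * f * t0), fs, low, high)
    i <- (5 * fs):(n - 5 * fs)
    max(abs(y[i])) / 1
  }
  expect_gte(ratio(5, 0.5, 10), 0.9)    # in the PPG passband
  expect_lte(ratio(40, 0.5, 10), 0.1)   # in the stopband
  expect_gte(ratio(10, 0.5, 20), 0.9)   # ECG band keeps 10 Hz
  # zero phase: cross-correlation argmax of a 2 Hz tone vs its filtered
  # version is at lag 0
  x <- sin(2 * pi * 2 * t0)
  y <- cheby2_bandpass(x, fs, 0.5, 10)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(cheby2_bandpass(x, fs, 10, 5), "low_hz")
  expect_error(cheby2_bandpass(x[1:10], fs, 0.5, 10), "too short")
})

test_that("R-peak detection recovers annotated beats", {
  expect_identical(detect_r_peaks(rep(0, 500), 125), integer(0))
  rec <- short_record(duration_s = 60, noise_sd = 0, seed = 21, hr_bpm = 60,
                      hrv_sd_s = 0.04)
  peaks <- detect_r_peaks(filter_ecg(rec$ecg, rec$fs), rec$fs)
  expect_true(all(diff(peaks) > 0.2 * rec$fs))
  expect_lte(abs(length(peaks) - 60), 1)
  err <- vapply(rec$annotations, function(a) min(abs(peaks - a)), numeric(1))
  expect_true(all(err <= 3))
})

test_that("R-peak detection tolerates moderate noise", {
  rec <- short_record(duration_s = 60, noise_sd = 0.05, seed = 22)
  peaks <- detect_r_peaks(filter_ecg(rec$ecg, rec$fs), rec$fs)
  err <- vapply(rec$annotations, function(a) min(abs(peaks - a)), numeric(1))
  expect_gte(mean(err <= 5), 0.95)
})

test_that("systolic detection finds one peak per pulse without double counts", {
  expect_identical(detect_systolic_peaks(rep(0, 500), 125), integer(0))
  rec <- short_record(duration_s = 60, noise_sd = 0, seed = 23, hr_bpm = 60,
                      hrv_sd_s = 0.04)
  peaks <- detect_systolic_peaks(filter_ppg(rec$ppg, rec$fs), rec$fs)
  expect_lte(abs(length(peaks) - 60), 1)
  target <- rec$annotations + round(0.24 * rec$fs)
  target <- target[target <= length(rec$ppg) - round(0.3 * rec$fs)]  # whole pulses only
  err <- vapply(target, function(a) min(abs(peaks - a)), numeric(1))
  expect_true(all(err <= 3))
  # strong dicrotic wave must not double-count
  pp <- c(sys_amp = 1, sys_width = 0.09, dicrotic_amp = 0.4,
          dicrotic_delay = 0.28, dicrotic_width = 0.09)
  rec2 <- gen_record(synth_params(duration_s = 60, noise_sd = 0, seed = 24,
                                  ppg_params = pp))
  p2 <- detect_systolic_peaks(filter_ppg(rec2$ppg, rec2$fs), rec2$fs)
  expect_lte(abs(length(p2) - length(rec2$annotations)), 1)
})

test_that("Alignment I recovers the pulse arrival lag", {
  rec <- short_record(duration_s = 60, noise_sd = 0.02, seed = 25, pat_s = 0.24)
  al <- align_pair(new_record(filter_ecg(rec$ecg, rec$fs),
                              filter_ppg(rec$ppg, rec$fs), rec$fs))
  expect_lte(abs(al$lag_samples - 30), 1)   # 0.24 s x 125 Hz
  expect_equal(length(al$ecg), length(al$ppg))
  expect_equal(length(al$ecg), length(rec$ecg) - al$lag_samples)

  rec0 <- short_record(duration_s = 60, noise_sd = 0.02, seed = 26, pat_s = 0)
  al0 <- align_pair(new_record(filter_ecg(rec0$ecg, rec0$fs),
                               filter_ppg(rec0$ppg, rec0$fs), rec0$fs))
  expect_true(al0$lag_samples %in% c(0L, 1L))

  two <- gen_record(synth_params(duration_s = 2.5, hr_bpm = 60, hrv_sd_s = 0,
                                 noise_sd = 0, seed = 27))
  expect_error(align_pair(two), "systolic peaks")
})

test_that("min-max normalization maps extremes and is idempotent", {
  expect_equal(normalize_minmax(c(2, 4, 3)), c(0, 1, 0.5))
  x <- rnorm(100)
  expect_equal(normalize_minmax(normalize_minmax(x)), normalize_minmax(x))
  expect_equal(normalize_minmax(c(2, 4, 3), c(-1, 1)), c(-1, 1, 0))
  expect_error(normalize_minmax(c(5, 5, 5)), "constant")
})

test_that("segmentation yields exact non-overlapping windows in order", {
  cfg <- default_config()
  fake <- list(ecg = seq_len(36800) / 36800, ppg = seq_len(36800) / 36800,
               fs = 125, record_id = "f")
  sg <- segment_record(fake, cfg)
  expect_equal(dim(sg$ecg), c(375L, 98L))
  expect_equal(as.vector(sg$ecg), fake$ecg[1:36750])  # order preserved
  cfg1 <- default_config(record_seconds_used = 3)
  one <- list(ecg = rnorm(375), ppg = rnorm(375), fs = 125, record_id = "g")
  expect_equal(ncol(segment_record(one, cfg1)$ecg), 1L)
  short <- list(ecg = rnorm(374), ppg = rnorm(374), fs = 125, record_id = "h")
  expect_error(segment_record(short, cfg1), "too short")
})

test_that("temporal split uses floor arithmetic and covers all segments", {
  cfg <- default_config()
  for (case in list(c(98, 58, 20, 20), c(10, 6, 2, 2), c(5, 3, 1, 1))) {
    sp <- split_segments(case[1], cfg)
    expect_equal(lengths(sp), c(train = case[2], val = case[3], test = case[4]))
    expect_equal(unname(sort(unlist(sp))), seq_len(case[1]))
    expect_true(max(sp$train) < min(sp$val) && max(sp$val) < min(sp$test))
  }
  expect_error(split_segments(4, cfg), "at least 5")
})

test_that("gap injection masks one contiguous training-portion span", {
  cfg <- default_config()
  rec <- gen_record(synth_params(duration_s = 300, seed = 31))
  sg <- preprocess_record(rec, cfg)
  sp <- split_segments(sg, cfg)
  ppg_before <- sg$ppg
  for (gap in c(1, 4)) {
    g <- inject_gap(sg, gap, seed = 77, split = sp, cfg = cfg)
    flat <- which(!as.vector(g$mask))
    expect_length(flat, gap * 125)
    expect_true(all(diff(flat) == 1))                      # contiguous
    expect_true(all(as.vector(g$ecg)[flat] == 0))          # zero-filled
    expect_lte(max(flat), length(sp$train) * 375)          # inside training
    expect_identical(g$ppg, ppg_before)                    # PPG untouched
    if (gap == 4) {
      segs <- unique((flat - 1) %/% 375 + 1)
      expect_gte(length(segs), 2L)                         # 500 > 375 samples
    }
  }
  g1 <- inject_gap(sg, 2, seed = 5, split = sp, cfg = cfg)
  g2 <- inject_gap(sg, 2, seed = 5, split = sp, cfg = cfg)
  expect_identical(g1$gap$start_sample, g2$gap$start_sample)
  expect_error(inject_gap(sg, 300, seed = 1, split = sp, cfg = cfg), "exceeds")
})

test_that("preprocessing conserves samples and bounds the PPG to [0,1]", {
  cfg <- default_config()
  rec <- gen_record(synth_params(duration_s = 300, seed = 32))
  sg <- preprocess_record(rec, cfg)
  expect_equal(ncol(sg$ecg) * sg$seg_len, cfg$record_seconds_used * cfg$fs)
  expect_true(all(sg$ppg >= 0 & sg$ppg <= 1))
  expect_true(all(sg$ecg >= 0 & sg$ecg <= 1))
})
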