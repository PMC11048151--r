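test_that("zero-jitter beat times follow the closed form", {
  p <- synth_params(duration_s = 10, hr_bpm = 60, hrv_sd_s = 0, seed = 1)
  bt <- gen_beat_times(p)
  expect_equal(bt, seq(0.5, 9.5, by = 1))  # 0.5 s first-beat offset, 1 s IBI
  expect_length(bt, 10L)
})

test_that("beat generation is seeded and statistically calibrated", {
  p <- synth_params(duration_s = 300, hr_bpm = 75, hrv_sd_s = 0.05, seed = 42)
  bt1 <- gen_beat_times(p)
  bt2 <- gen_beat_times(p)
  expect_identical(bt1, bt2)
  ibi <- diff(bt1)
  expect_lt(abs(mean(ibi) - 60 / 75), 3 * 0.05 / sqrt(length(ibi)))
  expect_true(all(ibi >= 0.3))
  expect_error(gen_beat_times(synth_params(duration_s = 0.5, hr_bpm = 60)),
               "duration")
})

test_that("noise-free ECG peaks at the R-wave center", {
  p <- synth_params(duration_s = 3, hr_bpm = 30, hrv_sd_s = 0, noise_sd = 0,
                    seed = 1)
  ecg <- gen_ecg(1.0, p)
  expect_equal(which.max(ecg), round(1.0 * p$fs) + 1L)
  # per-beat maxima of a full record sit on the annotations
  rec <- gen_record(synth_params(duration_s = 20, hrv_sd_s = 0, noise_sd = 0,
                                 seed = 2))
  for (a in rec$annotations) {
    w <- max(1, a - 20):min(length(rec$ecg), a + 20)
    expect_lte(abs(w[which.max(rec$ecg[w])] - a), 1L)
  }
})

test_that("empty beat train leaves pure noise at the configured SD", {
  p <- synth_params(duration_s = 40, noise_sd = 0.05, seed = 3)
  e <- gen_ecg(numeric(0), p)
  expect_equal(sd(e), 0.05, tolerance = 0.05)
  expect_identical(e, gen_ecg(numeric(0), p))  # seeded determinism
})

test_that("PPG systolic peak trails the R peak by the pulse arrival time", {
  for (pat in c(0.24, 0)) {
    p <- synth_params(duration_s = 30, hrv_sd_s = 0, noise_sd = 0,
                      pat_s = pat, seed = 4)
    bt <- gen_beat_times(p)
    ecg <- gen_ecg(bt, p)
    ppg <- gen_ppg(bt, p)
    lags <- vapply(bt[bt < 28], function(b) {
      w <- round(b * p$fs):round((b + 0.45) * p$fs) + 1L
      we <- round((b - 0.1) * p$fs):round((b + 0.1) * p$fs) + 1L
      (w[which.max(ppg[w])] - we[which.max(ecg[we])])
    }, numeric(1))
    expect_lte(abs(median(lags) - pat * p$fs), 1)
  }
})

test_that("zero dicrotic amplitude gives single-lobed pulses", {
  pp <- c(sys_amp = 1, sys_width = 0.09, dicrotic_amp = 0,
          dicrotic_delay = 0.28, dicrotic_width = 0.09)
  p <- synth_params(duration_s = 10, hr_bpm = 60, hrv_sd_s = 0, noise_sd = 0,
                    ppg_params = pp, seed = 5)
  ppg <- gen_ppg(gen_beat_times(p), p)
  # count local maxima above half height (plateau-safe): one per beat
  locmax <- which(ppg > c(-Inf, head(ppg, -1)) & ppg >= c(tail(ppg, -1), Inf))
  expect_equal(sum(ppg[locmax] > 0.5), 10L)
})

test_that("gen_record has the exact length and annotation count", {
  p <- synth_params(duration_s = 294, seed = 6, hr_bpm = 72)
  rec <- gen_record(p)
  expect_length(rec, 294L * 125L)
  expect_equal(length(rec$annotations), 294 * 72 / 60, tolerance = 0.02)
  rec2 <- gen_record(p)
  expect_identical(rec$ecg, rec2$ecg)
  expect_identical(rec$annotations, rec2$annotations)
})

test_that("simulated corpora are reproducible and id-stable", {
  a <- simulate_records(3, seed = 9, duration_s = 20)
  b <- simulate_records(3, seed = 9, duration_s = 20)
  expect_identical(lapply(a, `[[`, "ecg"), lapply(b, `[[`, "ecg"))
  expect_identical(vapply(a, `[[`, character(1), "record_id"),
                   c("synth001", "synth002", "synth003"))
  c <- simulate_records(3, seed = 10, duration_s = 20)
  expect_false(identical(a[[1]]$ecg, c[[1]]$ecg))
})

test_that("generator parameter invariants are enforced", {
  expect_error(synth_params(hr_bpm = 0), "hr_bpm")
  expect_error(synth_params(pat_s = -0.1), "pat_s")
  wp <- matrix(c(2, -0.2, 0.04, -0.15, -0.04, 0.012, 1, 0, 0.014,
                 -0.2, 0.035, 0.014, 0.3, 0.28, 0.06),
               ncol = 3, byrow = TRUE,
               dimnames = list(c("P", "Q", "R", "S", "T"),
                               c("amp", "offset_s", "width_s")))
  expect_error(synth_params(wave_params = wp), "largest")
})
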