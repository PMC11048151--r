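#' Parameters for the synthetic paired ECG/PPG generator
#'
#' The generator emulates the features of real paired recordings that the
#' reconstruction pipeline depends on: a beat train with Gaussian
#' inter-beat-interval jitter (heart-rate variability), an ECG built as a
#' sum of five Gaussian deflections per beat (P, Q, R, S, T with the R wave
#' dominant), a PPG whose systolic (and optional dicrotic) pulse trails each
#' R peak by a fixed pulse arrival time, additive white Gaussian noise, and
#' an optional low-frequency baseline-wander sinusoid.
#'
#' Default morphology (amplitude, center offset from R in s, width in s):
#' P (0.15, -0.20, 0.04), Q (-0.15, -0.04, 0.012), R (1.0, 0, 0.014),
#' S (-0.2, 0.035, 0.014), T (0.3, 0.28, 0.06).  Default PPG pulse:
#' systolic amplitude 1.0 / width 0.09 s, dicrotic amplitude 0.25 delayed
#' 0.28 s / width 0.09 s.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_bpm Mean heart rate in beats per minute.
#' @param hrv_sd_s Standard deviation of the inter-beat-interval jitter (s).
#' @param pat_s Pulse arrival time: R peak to systolic peak lag (s).
#' @param noise_sd Additive white-noise SD relative to the unit R amplitude.
#' @param wave_params 5x3 matrix (rows P,Q,R,S,T; columns amplitude,
#'   offset_s, width_s).
#' @param ppg_params Named numeric vector: `sys_amp`, `sys_width`,
#'   `dicrotic_amp`, `dicrotic_delay`, `dicrotic_width`.
#' @param baseline_wander If `TRUE`, add a 0.25 Hz sinusoid of amplitude
#'   0.2 to both channels (exercises the 0.5 Hz high-pass edge).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A named list of class `synth_params`.
#' @export
synth_params <- function(duration_s = 300, fs = 125, hr_bpm = 75,
                         hrv_sd_s = 0.04, pat_s = 0.24, noise_sd = 0.02,
                         wave_params = NULL, ppg_params = NULL,
                         baseline_wander = FALSE, seed = 1L) {
  if (is.null(wave_params)) {
    wave_params <- matrix(
      c(0.15, -0.20, 0.040,
        -0.15, -0.04, 0.012,
        1.00,  0.00, 0.014,
        -0.20,  0.035, 0.014,
        0.30,  0.28, 0.060),
      ncol = 3, byrow = TRUE,
      dimnames = list(c("P", "Q", "R", "S", "T"),
                      c("amp", "offset_s", "width_s")))
  }
  if (is.null(ppg_params)) {
    ppg_params <- c(sys_amp = 1.0, sys_width = 0.09,
                    dicrotic_amp = 0.25, dicrotic_delay = 0.28,
                    dicrotic_width = 0.09)
  }
  p <- list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
            hrv_sd_s = hrv_sd_s, pat_s = pat_s, noise_sd = noise_sd,
            wave_params = wave_params, ppg_params = ppg_params,
            baseline_wander = isTRUE(baseline_wander),
            seed = as.integer(seed))
  if (p$fs <= 0) stop("fs must be positive")
  if (p$hr_bpm <= 0) stop("hr_bpm must be positive")
  if (p$pat_s < 0) stop("pat_s must be non-negative")
  if (p$hrv_sd_s < 0) stop("hrv_sd_s must be non-negative")
  if (p$noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(p$wave_params[, "width_s"] <= 0)) stop("wave widths must be positive")
  if (p$ppg_params[["sys_width"]] <= 0 || p$ppg_params[["dicrotic_width"]] <= 0) {
    stop("PPG pulse widths must be positive")
  }
  ramp <- p$wave_params["R", "amp"]
  if (any(abs(p$wave_params[, "amp"]) > ramp + 1e-12) || ramp <= 0) {
    stop("R must carry the largest (positive) wave amplitude")
  }
  class(p) <- "synth_params"
  p
}

#' Generate beat times with heart-rate variability
#'
#' Beat times start 0.5 s into the record (so edge beats are whole) and
#' advance by inter-beat intervals drawn from Normal(60/hr_bpm, hrv_sd_s),
#' truncated below at 0.3 s.
#'
#' @param params A [synth_params()] object.
#' @return Strictly increasing numeric vector of beat times (s) in
#'   `[0, duration_s)`.
#' @export
gen_beat_times <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  mean_ibi <- 60 / params$hr_bpm
  if (params$duration_s <= mean_ibi) {
    stop("duration_s must exceed one mean beat interval")
  }
  n_max <- ceiling(params$duration_s / 0.3) + 2L
  withr::with_seed(derive_seed(params$seed, "beat_times"), {
    ibi <- pmax(0.3, stats::rnorm(n_max, mean_ibi, params$hrv_sd_s))
    times <- 0.5 + cumsum(c(0, ibi))
    times[times < params$duration_s]
  })
}

# Sum of Gaussian bumps amp*exp(-(t - center)^2 / (2 width^2)) evaluated on
# the record's sample grid; each bump only touches +-6 widths for speed.
gaussian_train <- function(n, fs, centers, amps, widths) {
  y <- numeric(n)
  t0 <- (seq_len(n) - 1) / fs
  for (i in seq_along(centers)) {
    lo <- max(1L, floor((centers[i] - 6 * widths[i]) * fs) + 1L)
    hi <- min(n, ceiling((centers[i] + 6 * widths[i]) * fs) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] + amps[i] * exp(-(t0[idx] - centers[i])^2 / (2 * widths[i]^2))
  }
  y
}

#' Generate a synthetic ECG trace
#'
#' Each beat contributes five Gaussian deflections (P, Q, R, S, T) centered
#' at the beat time plus the per-wave offset; white Gaussian noise (and
#' optionally baseline wander) is added on top.  With zero noise the
#' per-beat maximum falls on the R wave center.
#'
#' @param beat_times Beat times in seconds (see [gen_beat_times()]).
#' @param params A [synth_params()] object.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
gen_ecg <- function(beat_times, params) {
  stopifnot(inherits(params, "synth_params"))
  if (length(beat_times) && (min(beat_times) < 0 ||
                             max(beat_times) >= params$duration_s)) {
    stop("beat times must lie within [0, duration_s)")
  }
  n <- round(params$duration_s * params$fs)
  wp <- params$wave_params
  y <- numeric(n)
  if (length(beat_times)) {
    centers <- rep(beat_times, each = nrow(wp)) + rep(wp[, "offset_s"], length(beat_times))
    amps <- rep(wp[, "amp"], length(beat_times))
    widths <- rep(wp[, "width_s"], length(beat_times))
    y <- gaussian_train(n, params$fs, centers, amps, widths)
  }
  y <- y + synth_extras(n, params, "ecg_noise")
  y
}

#' Generate a synthetic PPG trace
#'
#' Each beat contributes a systolic Gaussian pulse centered `pat_s` seconds
#' after the R peak and, if `dicrotic_amp > 0`, a smaller dicrotic pulse
#' delayed a further `dicrotic_delay` seconds.
#'
#' @inheritParams gen_ecg
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
gen_ppg <- function(beat_times, params) {
  stopifnot(inherits(params, "synth_params"))
  if (length(beat_times) && (min(beat_times) < 0 ||
                             max(beat_times) >= params$duration_s)) {
    stop("beat times must lie within [0, duration_s)")
  }
  n <- round(params$duration_s * params$fs)
  pp <- params$ppg_params
  y <- numeric(n)
  if (length(beat_times)) {
    sys_c <- beat_times + params$pat_s
    centers <- c(sys_c, sys_c + pp[["dicrotic_delay"]])
    amps <- c(rep(pp[["sys_amp"]], length(beat_times)),
              rep(pp[["dicrotic_amp"]], length(beat_times)))
    widths <- c(rep(pp[["sys_width"]], length(beat_times)),
                rep(pp[["dicrotic_width"]], length(beat_times)))
    keep <- amps != 0
    y <- gaussian_train(n, params$fs, centers[keep], amps[keep], widths[keep])
  }
  y <- y + synth_extras(n, params, "ppg_noise")
  y
}

# Additive noise and optional baseline wander, seeded per channel.
synth_extras <- function(n, params, stream) {
  extra <- numeric(n)
  if (params$noise_sd > 0) {
    extra <- extra + withr::with_seed(
      derive_seed(params$seed, stream),
      stats::rnorm(n, 0, params$noise_sd))
  }
  if (params$baseline_wander) {
    t0 <- (seq_len(n) - 1) / params$fs
    extra <- extra + 0.2 * sin(2 * pi * 0.25 * t0)
  }
  extra
}

#' Generate a full paired record with ground-truth beat annotations
#'
#' @param params A [synth_params()] object.
#' @return A [new_record()] with `annotations` set to the R-peak sample
#'   indices (`round(beat_time * fs) + 1`).
#' @export
gen_record <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  beats <- gen_beat_times(params)
  ecg <- gen_ecg(beats, params)
  ppg <- gen_ppg(beats, params)
  new_record(ecg, ppg, fs = params$fs,
             record_id = sprintf("synth%08d", params$seed),
             annotations = round(beats * params$fs) + 1L)
}

#' Simulate a corpus of paired records
#'
#' Draws one mean heart rate per record uniformly from `hr_range` and
#' generates each record with an independent child seed.
#'
#' @param n_records Number of records.
#' @param seed Master seed.
#' @param hr_range Range (bpm) from which per-record mean heart rates are
#'   drawn.
#' @param ... Further arguments passed to [synth_params()] (e.g.
#'   `duration_s`, `noise_sd`, `pat_s`).
#' @return List of [new_record()] objects.
#' @export
simulate_records <- function(n_records, seed = 1L, hr_range = c(60, 90), ...) {
  stopifnot(n_records >= 1L)
  hrs <- withr::with_seed(derive_seed(seed, "record_hr"),
                          stats::runif(n_records, hr_range[1], hr_range[2]))
  lapply(seq_len(n_records), function(i) {
    p <- synth_params(hr_bpm = hrs[i], seed = derive_seed(seed, paste0("record", i)), ...)
    rec <- gen_record(p)
    rec$record_id <- sprintf("synth%03d", i)
    rec
  })
}
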