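test_that("stitching is pure ordered concatenation", {
  s1 <- sin(1:375 / 10)
  s2 <- cos(1:375 / 10)
  out <- stitch(list(s1, s2))
  expect_length(out, 750L)
  expect_equal(out[1:375], s1)
  expect_equal(out[375:376], c(s1[375], s2[1]))  # no boundary smoothing
  expect_equal(stitch(list(s1)), s1)
  expect_equal(stitch(cbind(s1, s2)), c(s1, s2))
  expect_error(stitch(list()), "empty")
  expect_error(stitch(list(s1, s2[1:10])), "equal length")
})

test_that("cross-correlation alignment recovers pure integer shifts", {
  rec <- short_record(duration_s = 20, noise_sd = 0.01, seed = 41)
  ref <- normalize_minmax(rec$ecg)
  delay <- function(x, s) x[pmin(pmax(seq_along(x) - s, 1), length(x))]
  n <- length(ref)
  for (s in c(-60, -13, 0, 13, 125)) {
    shifted <- delay(ref, s)
    al <- xcorr_align(ref, shifted, max_lag_samples = 125)
    expect_equal(al$lag, -s)
    inner <- (abs(s) + 1):(n - abs(s))  # exclude edge-repaired samples
    expect_equal(pearson_r(ref[inner], al$aligned[inner]), 1)
  }
  expect_error(xcorr_align(rep(1, 100), rnorm(100), 10), "constant")
})

test_that("alignment never reduces correlation below the unaligned value", {
  rec <- short_record(duration_s = 20, noise_sd = 0.05, seed = 42)
  ref <- normalize_minmax(rec$ecg)
  noisy <- ref + rnorm(length(ref), 0, 0.1)
  al <- xcorr_align(ref, noisy, max_lag_samples = 50)
  expect_gte(pearson_r(ref, al$aligned), pearson_r(ref, noisy) - 1e-9)
})

test_that("pearson r matches hand-computed values", {
  a <- c(1, 2, 3)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  b <- rnorm(50)
  expect_equal(pearson_r(b, 3 * b + 2), 1)  # scale/offset invariance
  d <- rnorm(50)
  expect_equal(pearson_r(b, d), pearson_r(d, b))  # symmetry
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1, 1), "two samples")
})

test_that("rmse matches hand-computed values and the loss identity", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(rep(0, 4), rep(1, 4)), 1)
  expect_equal(rmse(c(1, 2), c(3, 4)), 2)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(rmse(x, y)^2, mse_loss(x, y), tolerance = 1e-12)
})

test_that("prd matches hand-computed values and its algebraic identity", {
  expect_equal(prd(1:5, 1:5), 0)
  expect_equal(prd(c(3, 4), c(0, 0)), 100)
  expect_equal(prd(c(2, 0), c(1, 0)), 50)
  x <- rnorm(64); y <- rnorm(64)
  expect_equal(prd(x, y), 100 * rmse(x, y) * sqrt(length(x)) / sqrt(sum(x^2)),
               tolerance = 1e-10)
  expect_error(prd(rep(0, 5), 1:5), "zero-energy")
})

test_that("frechet distance matches micro-examples and the brute oracle", {
  expect_equal(frechet_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(frechet_distance(0, 3), 3)
  expect_equal(frechet_distance(c(0, 1, 0), c(0, 0, 0)), 1)
  set.seed(99)
  for (i in 1:50) {
    a <- round(runif(sample(1:6, 1), -2, 2), 2)
    b <- round(runif(sample(1:6, 1), -2, 2), 2)
    expect_equal(frechet_distance(a, b), frechet_brute(a, b))
  }
  # warping can only help for equal lengths
  a <- rnorm(40); b <- rnorm(40)
  expect_lte(frechet_distance(a, b), max(abs(a - b)))
  expect_error(frechet_distance(numeric(0), 1), "non-empty")
})

test_that("record evaluation reports both alignment states coherently", {
  rec <- short_record(duration_s = 20, noise_sd = 0.01, seed = 43)
  ref <- normalize_minmax(rec$ecg)
  cfg <- default_config()
  perfect <- evaluate_record(ref, ref, cfg, record_id = "p")
  for (side in perfect) {
    expect_equal(side$r, 1)
    expect_equal(side$rmse, 0)
    expect_equal(side$prd, 0)
    expect_equal(side$fd, 0)
  }
  shifted <- ref[pmin(pmax(seq_along(ref) - 10, 1), length(ref))]
  ev <- evaluate_record(ref, shifted, cfg, record_id = "s")
  expect_gt(ev$aligned$r, ev$unaligned$r)
  expect_gt(ev$aligned$r, 0.999)
  expect_equal(ev$aligned$lag_samples, -10L)
  noisy <- ref + rnorm(length(ref), 0, 0.07)
  ev2 <- evaluate_record(ref, noisy, cfg)
  expect_equal(ev2$unaligned$rmse, 0.07, tolerance = 0.1)
})

test_that("experiment summaries aggregate mean and sample SD", {
  mk <- function(r) {
    rep <- list(r = r, rmse = 0.1, prd = 5, fd = 0.2, aligned = FALSE,
                lag_samples = 0L, record_id = "x")
    list(unaligned = rep, aligned = modifyList(rep, list(aligned = TRUE)))
  }
  s <- summarize_reports(list(mk(0.8), mk(0.9)), experiment = "I")
  row <- s[s$metric == "r" & s$alignment == "no", ]
  expect_equal(row$mean, 0.85)
  expect_equal(row$sd, sd(c(0.8, 0.9)))
  expect_equal(row$formatted, "0.850 ± 0.071")
  expect_true(all(s$n == 2))
  same <- summarize_reports(list(mk(0.8), mk(0.8), mk(0.8)))
  expect_true(all(same$sd == 0))
  expect_true(all(same$n == 3))
  expect_error(summarize_reports(list(mk(0.8))), "at least 2")
})
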