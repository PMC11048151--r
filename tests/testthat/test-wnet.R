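test_that("both variants satisfy the length and range contract", {
  X <- matrix(runif(375 * 8), 375, 8)
  for (v in c("wnet", "wnet_bilstm")) {
    m <- build_model(model_spec(v, seed = 3))
    Y <- predict(m, X)
    expect_equal(dim(Y), c(375L, 8L))
    expect_true(all(Y >= -1 & Y <= 1))   # Tanh output
  }
  m <- build_model(model_spec("wnet", seed = 3))
  expect_error(predict(m, matrix(0, 100, 2)), "in_len")
})

test_that("spec validation pins the reference hyperparameters", {
  expect_error(model_spec("wnet", kernel = 3), "fixed")
  expect_error(model_spec("wnet", dropout = 0.2), "fixed")
  expect_error(model_spec("wnet", in_len = 400), "fixed")
  s <- model_spec("wnet", kernel = 3, allow_nonstandard = TRUE)
  expect_equal(s$kernel, 3L)
  expect_error(model_spec("bogus"), "arg")
})

test_that("parameter counts are deterministic and monotone in capacity", {
  n_wnet <- count_parameters(build_model(model_spec("wnet", seed = 1)))
  n_bilstm <- count_parameters(build_model(model_spec("wnet_bilstm", seed = 1)))
  expect_gt(n_bilstm, n_wnet)  # strict superset of layers
  expect_equal(count_parameters(build_model(model_spec("wnet", seed = 9))),
               n_wnet)  # same spec, same count
  n3 <- count_parameters(build_model(model_spec("wnet", levels = 3, seed = 1)))
  expect_gt(n_wnet, n3)  # deeper network has more parameters
  # micro-oracle: a single conv 1->1, k=4, with bias
  expect_equal(ppg2ecg:::conv1d_param_count(1, 1, 4), 5)
})

test_that("the layer table matches the built model exactly", {
  for (v in c("wnet", "wnet_bilstm")) {
    spec <- model_spec(v, seed = 2)
    tab <- model_summary(spec)
    expect_equal(sum(tab$params),
                 count_parameters(build_model(spec)))  # conservation
    expect_equal(sum(grepl("down", tab$layer)), 8L)    # 2 U-blocks x 4
    expect_equal(sum(grepl("up", tab$layer)), 8L)
    expect_equal(sum(tab$type == "bilstm"), if (v == "wnet_bilstm") 1L else 0L)
    expect_equal(tab$out_len[nrow(tab)], 375L)
  }
})

test_that("weight initialization is seed-deterministic", {
  w1 <- ppg2ecg:::.wnet_get_state(build_model(model_spec("wnet", seed = 5))$ptr)
  w2 <- ppg2ecg:::.wnet_get_state(build_model(model_spec("wnet", seed = 5))$ptr)
  w3 <- ppg2ecg:::.wnet_get_state(build_model(model_spec("wnet", seed = 6))$ptr)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
})

test_that("one optimization step moves essentially every parameter tensor", {
  m <- build_model(model_spec("wnet", seed = 7))
  before <- ppg2ecg:::.wnet_tensors(m$ptr)
  X <- matrix(runif(375 * 8), 375, 8)
  Y <- matrix(runif(375 * 8), 375, 8)
  cfg <- default_config(epochs = 1L, batch_size = 8L)
  m <- train_model(m, X, Y, X, Y, cfg, seed = 1)
  after <- ppg2ecg:::.wnet_tensors(m$ptr)
  changed <- mapply(function(a, b) !identical(a, b), before, after)
  expect_gte(mean(changed), 0.99)
})

test_that("checkpoints round-trip through save and load", {
  m <- build_model(model_spec("wnet_bilstm", seed = 8))
  X <- matrix(runif(375 * 4), 375, 4)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_equal(predict(m2, X), predict(m, X))
  expect_equal(m2$spec$variant, "wnet_bilstm")
})

test_that("analytic gradients agree with central finite differences", {
  # small network, dropout disabled so the training-mode forward is smooth
  spec <- model_spec("wnet_bilstm", in_len = 48L, levels = 2L,
                     base_channels = 4L, dropout = 0, seed = 99,
                     allow_nonstandard = TRUE)
  m <- build_model(spec)
  set.seed(1)
  X <- matrix(runif(48 * 3), 48, 3)
  Y <- matrix(runif(48 * 3), 48, 3)
  ag <- ppg2ecg:::.wnet_loss_grad(m$ptr, X, Y, 1L)
  state <- ppg2ecg:::.wnet_get_state(m$ptr)
  sizes <- vapply(ag$grads, length, integer(1))
  offsets <- cumsum(c(0L, sizes))
  loss_at <- function(s) {
    ppg2ecg:::.wnet_set_state(m$ptr, s)
    mean((ppg2ecg:::.wnet_forward(m$ptr, X, TRUE) - Y)^2)
  }
  eps <- 1e-3
  set.seed(2)
  for (t in seq_along(sizes)) {
    for (j in sample(sizes[t], min(2L, sizes[t]))) {
      k <- offsets[t] + j
      s1 <- state; s1[k] <- s1[k] + eps
      s2 <- state; s2[k] <- s2[k] - eps
      fd <- (loss_at(s1) - loss_at(s2)) / (2 * eps)
      an <- ag$grads[[t]][j]
      # mixed tolerance: relative agreement plus an absolute floor for the
      # single-precision finite-difference noise
      expect_lt(abs(fd - an), 0.15 * (abs(fd) + abs(an)) + 5e-5,
                label = sprintf("gradient of %s[%d]", names(ag$grads)[t], j))
    }
  }
})

test_that("the BiLSTM variant can also overfit a single repeated pair", {
  rec <- short_record(duration_s = 20, noise_sd = 0.01, seed = 502)
  sg <- preprocess_record(rec, default_config(record_seconds_used = 18))
  ppg <- matrix(rep(sg$ppg[, 3], 8), 375, 8)
  ecg <- matrix(rep(sg$ecg[, 3], 8), 375, 8)
  cfg <- default_config(epochs = 500L, batch_size = 8L,
                        learning_rate = 1e-2, lr_decay_step = 250L)
  m <- build_model(model_spec("wnet_bilstm", seed = 503))
  m <- train_model(m, ppg, ecg, ppg, ecg, cfg, seed = 504)
  expect_lt(min(m$history$train_loss), 1e-3)
})
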