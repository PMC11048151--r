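#' Mean squared error between a reference and a reconstruction
#'
#' The training objective: the mean of squared per-sample differences.
#' With `mask` supplied and `masked = TRUE`, the mean runs over mask-true
#' samples only (gap samples excluded).
#'
#' @param reference,reconstructed Equal-length numeric vectors (or
#'   matrices).
#' @param mask Optional logical vector/matrix of the same shape
#'   (`TRUE` = include).
#' @param masked If `TRUE`, average over `mask`-true entries only.
#' @return Scalar loss.
#' @export
mse_loss <- function(reference, reconstructed, mask = NULL, masked = FALSE) {
  if (length(reference) != length(reconstructed)) {
    stop("reference and reconstruction must have equal length")
  }
  if (length(reference) < 1L) stop("need at least one sample")
  d2 <- (as.numeric(reference) - as.numeric(reconstructed))^2
  if (masked) {
    if (is.null(mask)) stop("masked = TRUE requires a mask")
    mask <- as.logical(mask)
    if (!any(mask)) stop("masked loss undefined for an all-false mask")
    return(mean(d2[mask]))
  }
  mean(d2)
}

#' Step-decay learning-rate schedule
#'
#' `base * factor^floor(epoch / step)`: the rate starts at `base` (0.001)
#' and decays by `factor` (0.1) every `step` (100) epochs.
#'
#' @param epoch Zero-based epoch index.
#' @param base Initial learning rate.
#' @param factor Multiplicative decay.
#' @param step Epochs between decays.
#' @return Learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, base = 0.001, factor = 0.1, step = 100) {
  stopifnot(all(epoch >= 0))
  base * factor^(floor(epoch / step))
}

#' Train a reconstruction model
#'
#' Adam optimization of the mean-squared-error objective with seeded batch
#' shuffling and the step-decay schedule of [lr_schedule()].  After the last
#' epoch the model weights are restored to the checkpoint with minimum
#' validation loss.  Gap samples are included in the loss as zero-filled
#' targets by default; set `masked_loss = TRUE` (or in `cfg`) to exclude
#' them.
#'
#' @param model A [build_model()] instance (mutated in place and returned).
#' @param train_ppg,train_ecg `in_len x n` matrices of paired training
#'   segments (one segment per column).
#' @param val_ppg,val_ecg Validation segments, same layout.
#' @param cfg A [default_config()] list supplying `epochs`, `batch_size`,
#'   `learning_rate`, `lr_decay_factor`, `lr_decay_step`, `masked_loss`.
#' @param train_mask Optional logical matrix marking present ECG samples
#'   (`FALSE` = gap); required shape equals `train_ecg`.
#' @param seed Seed for batch shuffling and dropout (defaults to
#'   `cfg$seed`).
#' @return The trained model; `model$history` holds per-epoch `train_loss`,
#'   `val_loss`, `lr`, the selected `best_epoch`, `best_val_loss`, and the
#'   optimizer constants (`adam_beta1` 0.9, `adam_beta2` 0.999,
#'   `adam_eps` 1e-8).
#' @export
train_model <- function(model, train_ppg, train_ecg, val_ppg, val_ecg,
                        cfg = default_config(), train_mask = NULL,
                        seed = NULL) {
  stopifnot(inherits(model, "wnet_model"))
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "train")
  if (ncol(train_ppg) < 1L) stop("empty training set")
  if (is.null(train_mask)) {
    train_mask <- matrix(TRUE, nrow = nrow(train_ecg), ncol = ncol(train_ecg))
  }
  stopifnot(dim(train_mask) == dim(train_ecg),
            dim(train_ppg) == dim(train_ecg))
  hist <- .wnet_train(model$ptr, train_ppg, train_ecg, train_mask,
                      val_ppg, val_ecg,
                      as.integer(cfg$epochs), as.integer(cfg$batch_size),
                      cfg$learning_rate, cfg$lr_decay_factor,
                      as.integer(cfg$lr_decay_step),
                      as.integer(seed), isTRUE(cfg$masked_loss))
  hist$adam_beta1 <- 0.9
  hist$adam_beta2 <- 0.999
  hist$adam_eps <- 1e-8
  hist$seed <- as.integer(seed)
  model$history <- hist
  model
}

#' Save / load model weights
#'
#' Weights (including batch-norm running statistics) are written as an
#' uncompressed numeric blob with the spec serialized alongside as JSON, so
#' a checkpoint is reproducible from the pair.
#'
#' @param model A `wnet_model`.
#' @param path Checkpoint path (an `.json` sidecar with the spec is written
#'   next to it).
#' @return `path` (save) or a restored `wnet_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wnet_model"))
  state <- .wnet_get_state(model$ptr)
  saveRDS(list(spec = unclass(model$spec), state = state,
               history = model$history), path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  spec <- do.call(model_spec, c(blob$spec, list(allow_nonstandard = TRUE)))
  model <- build_model(spec)
  .wnet_set_state(model$ptr, blob$state)
  model$history <- blob$history
  model
}
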