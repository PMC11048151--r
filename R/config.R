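#' Default run configuration
#'
#' Returns the configuration that reproduces the reference experimental
#' setup: 125 Hz sampling, 3-s segments (375 samples), first 294 s of each
#' record, a contiguous 60/20/20 train/validation/test split, one injected
#' ECG gap per record, and Adam training at learning rate 0.001 decaying
#' by 0.1 every 100 epochs for 500 epochs with batch size 128.
#'
#' @param ... Named overrides of any default entry.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fs = 125,
    segment_seconds = 3,
    record_seconds_used = 294,
    split_fractions = c(train = 0.6, val = 0.2, test = 0.2),
    gap_seconds = 1,
    variant = "wnet",
    epochs = 500L,
    batch_size = 128L,
    learning_rate = 0.001,
    lr_decay_factor = 0.1,
    lr_decay_step = 100L,
    masked_loss = FALSE,
    max_align_lag_seconds = 1,
    allow_any_gap = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys fall back to [default_config()].  `split_fractions`
#' may be given as a three-element list/vector (train, val, test).
#'
#' @param path Path to a flat key-value YAML file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$split_fractions)) {
    raw$split_fractions <- as.numeric(unlist(raw$split_fractions))
  }
  do.call(default_config, raw)
}

validate_config <- function(cfg) {
  sf <- as.numeric(cfg$split_fractions)
  if (length(sf) != 3L || any(sf <= 0) || abs(sum(sf) - 1) > 1e-9) {
    stop("split_fractions must be three positive numbers summing to 1")
  }
  names(sf) <- c("train", "val", "test")
  cfg$split_fractions <- sf
  if (!is.numeric(cfg$fs) || cfg$fs <= 0) stop("fs must be positive")
  seg_len <- cfg$segment_seconds * cfg$fs
  if (abs(seg_len - round(seg_len)) > 1e-9) {
    stop("segment_seconds * fs must be an integer number of samples")
  }
  if (!isTRUE(cfg$allow_any_gap) && !(cfg$gap_seconds %in% c(1, 2, 3, 4))) {
    stop("gap_seconds must be one of 1, 2, 3, 4 (set allow_any_gap = TRUE to override)")
  }
  if (cfg$gap_seconds <= 0) stop("gap_seconds must be positive")
  if (!(cfg$variant %in% c("wnet", "wnet_bilstm"))) {
    stop("variant must be 'wnet' or 'wnet_bilstm'")
  }
  for (k in c("epochs", "batch_size", "lr_decay_step")) {
    cfg[[k]] <- as.integer(cfg[[k]])
    if (cfg[[k]] < 1L) stop(k, " must be a positive integer")
  }
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$max_align_lag_seconds <= 0) stop("max_align_lag_seconds must be positive")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}

# Number of samples per segment under a config.
segment_samples <- function(cfg) as.integer(round(cfg$segment_seconds * cfg$fs))
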