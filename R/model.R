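#' Hyperparameter specification for a WNet / WNet-BiLSTM model
#'
#' A `model_spec` fully determines a network instance.  The architecture is
#' two cascaded 1-D convolutional U-blocks: each U-block has `levels`
#' down-sampling blocks (conv kernel 4, stride 2, batch-norm, ReLU; channel
#' schedule `base_channels * 2^level`) and `levels` up-sampling blocks
#' (transposed conv kernel 4, stride 2, batch-norm, ReLU) with skip
#' concatenation from the same-level encoder output.  Dropout (rate 0.5)
#' sits at each U-block bottleneck.  The input (375 samples by default) is
#' constant-padded to the next multiple of `2^levels` (384) on entry and
#' cropped back on exit; the second U-block's output passes a final 1x1
#' convolution activated by Tanh.  The `wnet_bilstm` variant additionally
#' runs one bidirectional LSTM (hidden size = half the bottleneck channels
#' per direction) over the second U-block's bottleneck time steps.
#'
#' Kernel 4 / stride 2 and dropout 0.5 are fixed by the reference design;
#' deviating requires `allow_nonstandard = TRUE`.
#'
#' @param variant `"wnet"` or `"wnet_bilstm"`.
#' @param in_len Input/output segment length in samples (default 375).
#' @param levels Down/up blocks per U-block (default 4).
#' @param base_channels Channels of the first encoder block (default 32).
#' @param kernel,stride Convolution kernel size and stride (fixed 4 / 2).
#' @param dropout Dropout rate at the bottlenecks (fixed 0.5).
#' @param seed Integer seed for weight initialization.
#' @param allow_nonstandard Permit non-reference kernel/stride/dropout/in_len.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(variant = c("wnet", "wnet_bilstm"), in_len = 375L,
                       levels = 4L, base_channels = 32L, kernel = 4L,
                       stride = 2L, dropout = 0.5, seed = 1L,
                       allow_nonstandard = FALSE) {
  variant <- match.arg(variant)
  spec <- list(variant = variant, in_len = as.integer(in_len),
               levels = as.integer(levels),
               base_channels = as.integer(base_channels),
               kernel = as.integer(kernel), stride = as.integer(stride),
               dropout = dropout, seed = as.integer(seed))
  if (!allow_nonstandard) {
    if (spec$kernel != 4L || spec$stride != 2L) {
      stop("kernel/stride are fixed at 4/2 (set allow_nonstandard = TRUE to override)")
    }
    if (spec$dropout != 0.5) {
      stop("dropout is fixed at 0.5 (set allow_nonstandard = TRUE to override)")
    }
    if (spec$in_len != 375L) {
      stop("in_len is fixed at 375 (set allow_nonstandard = TRUE to override)")
    }
  }
  if (spec$levels < 1L || spec$base_channels < 1L) {
    stop("levels and base_channels must be positive")
  }
  if (spec$base_channels %% 2L != 0L && variant == "wnet_bilstm") {
    stop("base_channels must be even for the BiLSTM bottleneck")
  }
  class(spec) <- "model_spec"
  spec
}

#' Build a model instance from a specification
#'
#' Allocates and seeds the network weights; the returned object holds the
#' native engine handle plus the spec.
#'
#' @param spec A [model_spec()].
#' @return An object of class `wnet_model`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  ptr <- .wnet_create(spec$variant, spec$in_len, spec$levels,
                      spec$base_channels, spec$kernel, spec$stride,
                      spec$dropout, spec$seed)
  structure(list(ptr = ptr, spec = spec, history = NULL),
            class = "wnet_model")
}

#' @export
print.wnet_model <- function(x, ...) {
  cat(sprintf("<wnet_model '%s'>  in_len %d, %d levels, base %d channels, %s parameters%s\n",
              x$spec$variant, x$spec$in_len, x$spec$levels,
              x$spec$base_channels,
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Reconstruct ECG segments from PPG segments
#'
#' Runs the network in evaluation mode (batch-norm running statistics, no
#' dropout).
#'
#' @param object A `wnet_model`.
#' @param ppg Numeric matrix, `in_len x n_segments` (one segment per
#'   column, values in `[0, 1]`), or a single segment vector.
#' @param ... Unused.
#' @return Matrix of reconstructed ECG segments, same shape; values in
#'   `[-1, 1]` (Tanh output).
#' @export
predict.wnet_model <- function(object, ppg, ...) {
  if (is.vector(ppg)) ppg <- matrix(ppg, ncol = 1L)
  if (nrow(ppg) != object$spec$in_len) {
    stop("segment length ", nrow(ppg), " != model in_len ", object$spec$in_len)
  }
  .wnet_forward(object$ptr, ppg, FALSE)
}

#' Count trainable parameters
#'
#' @param model A `wnet_model`.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "wnet_model"))
  .wnet_nparams(model$ptr)
}

# Parameter count of one 1-D conv layer (weights + bias).
conv1d_param_count <- function(in_ch, out_ch, kernel, bias = TRUE) {
  out_ch * in_ch * kernel + if (bias) out_ch else 0L
}

#' Layer table for a model specification
#'
#' Enumerates every layer with its output shape and parameter count; the
#' per-row parameter totals sum to [count_parameters()] of the built model.
#'
#' @param spec A [model_spec()].
#' @return A data frame with columns `layer`, `type`, `out_channels`,
#'   `out_len`, `params`.
#' @export
model_summary <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  lev <- spec$levels; Fb <- spec$base_channels; k <- spec$kernel
  block <- 2L^lev
  lpad <- ceiling(spec$in_len / block) * block
  rows <- list()
  add <- function(layer, type, out_ch, out_len, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, type = type, out_channels = out_ch,
      out_len = out_len, params = params, stringsAsFactors = FALSE)
  }
  down_out <- function(l) Fb * 2L^(l - 1L)
  up_out <- function(l) if (l < lev) Fb * 2L^(lev - 1L - l) else Fb
  up_in <- function(l) if (l == 1L) down_out(lev) else 2L * up_out(l - 1L)
  for (u in 1:2) {
    cin <- if (u == 1L) 1L else Fb
    len <- lpad
    for (l in seq_len(lev)) {
      ci <- if (l == 1L) cin else down_out(l - 1L)
      co <- down_out(l)
      len <- len %/% spec$stride
      add(sprintf("u%d.down%d", u, l), "conv_bn_relu", co, len,
          conv1d_param_count(ci, co, k) + 2L * co)
    }
    if (u == 2L && spec$variant == "wnet_bilstm") {
      H <- down_out(lev) %/% 2L
      add("u2.bilstm", "bilstm", down_out(lev), len,
          2L * (4L * H * down_out(lev) + 4L * H * H + 4L * H))
    }
    add(sprintf("u%d.dropout", u), "dropout", down_out(lev), len, 0L)
    for (l in seq_len(lev)) {
      ci <- up_in(l); co <- up_out(l)
      len <- len * spec$stride
      add(sprintf("u%d.up%d", u, l), "tconv_bn_relu", co, len,
          conv1d_param_count(ci, co, k) + 2L * co)
    }
  }
  add("final", "conv_tanh", 1L, spec$in_len, conv1d_param_count(Fb, 1L, 1L))
  do.call(rbind, rows)
}
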