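# Per-layer parameter statistics and analytic FLOP estimates.
#
# FLOP convention: counts are multiply-accumulate operations (MACs); one
# MAC is reported as 2 FLOPs. Activations, pooling and softmax are counted
# as zero MACs.

#' Trainable parameters of a fully connected layer
#'
#' `n_in * n_out` weights plus `n_out` biases (e.g. 256 inputs, 10 outputs
#' with bias: 2,570).
#'
#' @param n_in,n_out layer widths.
#' @param bias include a bias vector?
#' @return parameter count.
#' @export
param_count_linear <- function(n_in, n_out, bias = TRUE) {
  n_in * n_out + if (bias) n_out else 0L
}

#' Trainable parameters of a 2-D convolution layer
#'
#' `out * (in * M * N)` weights plus `out` biases (e.g. 3 input channels,
#' 64 output channels, 3x3 kernel with bias: 1,792).
#'
#' @param in_channels,out_channels channel counts.
#' @param M,N kernel height and width.
#' @param bias include a bias vector?
#' @return parameter count.
#' @export
param_count_conv2d <- function(in_channels, out_channels, M = 3L, N = M, bias = TRUE) {
  out_channels * in_channels * M * N + if (bias) out_channels else 0L
}

# 2 * 4 * (h * (h + d) + h): two directions, four gates each.
param_count_bilstm <- function(input_size, hidden_size) {
  2L * 4L * (hidden_size * (hidden_size + input_size) + hidden_size)
}

#' Per-layer parameter statistics
#'
#' Enumerates every trainable array of the configured architecture, grouped
#' by layer, with output shapes. The total equals the length of the
#' flattened parameter vector from [init_parameters()] exactly.
#'
#' @param config a [model_config()].
#' @return list with `table` (data frame: layer, output_shape, params) and
#'   `total`.
#' @export
count_parameters <- function(config) {
  cfg <- config
  rows <- list()
  add <- function(layer, shape, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, output_shape = paste0("(", paste(shape, collapse = ", "), ")"),
      params = params, stringsAsFactors = FALSE)
  }
  d <- cfg$d_model
  if ("image" %in% cfg$modalities) {
    sz <- cfg$image$size; c_in <- cfg$image$channels; kk <- cfg$image$kernel
    for (k in seq_along(cfg$image$blocks)) {
      c_out <- cfg$image$blocks[k]
      sz <- sz - kk + 1L
      add(sprintf("Conv2d (in_channels = %d, out_channels = %d)", c_in, c_out),
          c(c_out, sz, sz), param_count_conv2d(c_in, c_out, kk))
      add("ReLU", c(c_out, sz, sz), 0L)
      sz <- sz %/% 2L
      add("MaxPool2d (kernel_size = 2)", c(c_out, sz, sz), 0L)
      c_in <- c_out
    }
    add("GlobalAvgPool", c(c_in), 0L)
    add("Linear (image projection)", c(d), param_count_linear(c_in, d))
  }
  if ("series" %in% cfg$modalities) {
    hid <- cfg$series$hidden; D <- cfg$series$channels
    add(sprintf("Bi-LSTM (input_size = %d, hidden_size = %d)", D, hid),
        c(hid), param_count_bilstm(D, hid))
    add("Linear (series projection)", c(d), param_count_linear(hid, d))
  }
  if ("text" %in% cfg$modalities) {
    add(sprintf("Embedding (vocab = %d)", cfg$text$vocab), c(d),
        cfg$text$vocab * d)
    add("MultiHeadSelfAttention (text)", c(d),
        4L * param_count_linear(d, d, bias = FALSE))
  }
  for (m in cfg$modalities) {
    add(sprintf("Linear (fusion projection, %s)", m), c(d),
        param_count_linear(d, d, bias = FALSE))
  }
  add("MultiHeadSelfAttention (fusion)", c(length(cfg$modalities), d),
      4L * param_count_linear(d, d, bias = FALSE))
  add("Linear (fusion scores)", c(length(cfg$modalities)),
      param_count_linear(d, 1L, bias = FALSE))
  add("Softmax (fusion weights)", c(length(cfg$modalities)), 0L)
  add("Linear (classifier)", c(cfg$n_classes),
      param_count_linear(d, cfg$n_classes))
  table <- do.call(rbind, rows)
  list(table = table, total = sum(table$params))
}

#' Analytic multiply-add (MAC) and FLOP estimate
#'
#' Per-layer MAC counts for one forward pass, with 1 MAC = 2 FLOPs.
#' Deterministic in the config and the stated input sizes.
#'
#' @param config a [model_config()].
#' @param series_length time steps T assumed for the series branch.
#' @param text_length token count assumed for the text branch.
#' @return list with `table` (layer, macs, flops), `total_macs`,
#'   `total_flops`.
#' @export
estimate_flops <- function(config, series_length = 32L, text_length = 25L) {
  cfg <- config
  rows <- list()
  add <- function(layer, macs) {
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, macs = macs,
                                             flops = 2 * macs,
                                             stringsAsFactors = FALSE)
  }
  d <- cfg$d_model
  if ("image" %in% cfg$modalities) {
    sz <- cfg$image$size; c_in <- cfg$image$channels; kk <- cfg$image$kernel
    for (k in seq_along(cfg$image$blocks)) {
      c_out <- cfg$image$blocks[k]
      out_sz <- sz - kk + 1L
      add(sprintf("Conv2d %d->%d", c_in, c_out),
          conv_macs(sz, sz, kk, kk, c_in, c_out))
      sz <- out_sz %/% 2L
      c_in <- c_out
    }
    add("Linear (image projection)", c_in * d)
  }
  if ("series" %in% cfg$modalities) {
    hid <- cfg$series$hidden; D <- cfg$series$channels
    add("Bi-LSTM", 2 * series_length * 4 * hid * (hid + D))
    add("Linear (series projection)", hid * d)
  }
  if ("text" %in% cfg$modalities) {
    n <- text_length
    add("MultiHeadSelfAttention (text)", 4 * n * d * d + 2 * n * n * d)
  }
  k <- length(cfg$modalities)
  add("Fusion projections", k * d * d)
  add("MultiHeadSelfAttention (fusion)", 4 * k * d * d + 2 * k * k * d)
  add("Fusion scores + weighted fuse", 2 * k * d)
  add("Linear (classifier)", cfg$n_classes * d)
  table <- do.call(rbind, rows)
  list(table = table, total_macs = sum(table$macs), total_flops = 2 * sum(table$macs))
}

#' MACs of a valid 2-D convolution
#'
#' `(H - M + 1) * (W - N + 1) * M * N * C_in * C_out`; a 1x1 kernel on one
#' channel costs exactly `H * W` MACs.
#'
#' @param H,W input spatial size.
#' @param M,N kernel size.
#' @param c_in,c_out channel counts.
#' @return MAC count.
#' @export
conv_macs <- function(H, W, M, N, c_in = 1L, c_out = 1L) {
  (H - M + 1) * (W - N + 1) * M * N * c_in * c_out
}
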