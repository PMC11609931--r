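# Bidirectional LSTM encoder for the physiological time series.
#
# Gate equations (sigma = logistic, o = elementwise product):
#   i_t = sigma(W_i [h_{t-1}, x_t] + b_i)        input gate
#   f_t = sigma(W_f [h_{t-1}, x_t] + b_f)        forget gate
#   g_t = tanh (W_c [h_{t-1}, x_t] + b_c)        candidate cell state
#   c_t = f_t o c_{t-1} + i_t o g_t              cell update
#   o_t = sigma(W_o [h_{t-1}, x_t] + b_o)        output gate
#   h_t = o_t o tanh(c_t)
# The backward direction runs the same recursion over the reversed series
# (zero-initialised state), and the merged output at each step is the
# elementwise SUM of the two directions' hidden states.
#
# Internally the four gates are stacked into one (4h x (h + D)) matrix in
# the row order [i; f; o; g] and a batch of series is processed jointly as
# a (T, D, B) array, one matrix multiply per time step.

# One direction over a (T, D, B) batch with stacked parameters.
lstm_seq_forward <- function(X, Ws, bs, hid) {
  d <- dim(X); T_len <- d[1L]; D <- d[2L]; B <- d[3L]
  H_prev <- matrix(0, hid, B); C_prev <- matrix(0, hid, B)
  i_r <- seq_len(hid); f_r <- hid + i_r; o_r <- 2L * hid + i_r; g_r <- 3L * hid + i_r
  steps <- vector("list", T_len)
  Hseq <- array(0, c(T_len, hid, B))
  for (t in seq_len(T_len)) {
    Z <- rbind(H_prev, matrix(X[t, , ], D, B))
    A <- Ws %*% Z + bs
    i_g <- sigmoid(A[i_r, , drop = FALSE])
    f_g <- sigmoid(A[f_r, , drop = FALSE])
    o_g <- sigmoid(A[o_r, , drop = FALSE])
    g_g <- tanh(A[g_r, , drop = FALSE])
    C_t <- f_g * C_prev + i_g * g_g
    tc <- tanh(C_t)
    H_t <- o_g * tc
    steps[[t]] <- list(Z = Z, i = i_g, f = f_g, o = o_g, g = g_g,
                       C_prev = C_prev, tc = tc)
    Hseq[t, , ] <- H_t
    H_prev <- H_t; C_prev <- C_t
  }
  list(Hseq = Hseq, steps = steps, hid = hid, D = D, B = B, T_len = T_len)
}

# BPTT for one direction. dHseq: (T, hid, B) gradient w.r.t. that
# direction's hidden outputs. Returns stacked dWs, dbs.
lstm_seq_backward <- function(dHseq, fwd) {
  hid <- fwd$hid; B <- fwd$B; T_len <- fwd$T_len
  i_r <- seq_len(hid); f_r <- hid + i_r; o_r <- 2L * hid + i_r; g_r <- 3L * hid + i_r
  dWs <- matrix(0, 4L * hid, hid + fwd$D)
  dbs <- numeric(4L * hid)
  dH_next <- matrix(0, hid, B); dC_next <- matrix(0, hid, B)
  for (t in rev(seq_len(T_len))) {
    st <- fwd$steps[[t]]
    dH <- matrix(dHseq[t, , ], hid, B) + dH_next
    dO <- dH * st$tc
    dC <- dC_next + dH * st$o * (1 - st$tc^2)
    dF <- dC * st$C_prev
    dI <- dC * st$g
    dG <- dC * st$i
    dC_next <- dC * st$f
    dA <- rbind(dI * st$i * (1 - st$i),
                dF * st$f * (1 - st$f),
                dO * st$o * (1 - st$o),
                dG * (1 - st$g^2))
    dWs <- dWs + tcrossprod(dA, st$Z)
    dbs <- dbs + rowSums(dA)
    dZ <- crossprod(fwd$Ws, dA)
    dH_next <- dZ[seq_len(hid), , drop = FALSE]
  }
  list(dWs = dWs, dbs = dbs)
}

stack_lstm_params <- function(p) {
  list(Ws = rbind(p$W_i, p$W_f, p$W_o, p$W_c),
       bs = c(p$b_i, p$b_f, p$b_o, p$b_c))
}

#' One LSTM cell update
#'
#' Applies the input/forget/output gate equations and the cell update to a
#' single time step (see the gate formulas in the package documentation of
#' this file). The hidden state satisfies `|h| <= 1` elementwise since it
#' is a product of a sigmoid and a tanh.
#'
#' @param x_t input vector at the current step.
#' @param prev list with `h` and `c`, the previous hidden and cell state.
#' @param p list with matrices `W_i`, `W_f`, `W_o`, `W_c`
#'   (`hidden x (hidden + input)`, acting on the concatenation
#'   `[h_{t-1}, x_t]`) and bias vectors `b_i`, `b_f`, `b_o`, `b_c`.
#' @return list with the new `h` and `c`.
#' @export
lstm_step <- function(x_t, prev, p) {
  hid <- length(prev$h)
  if (ncol(p$W_i) != hid + length(x_t)) {
    stopf("lstm_step: W_i has %d columns, expected hidden + input = %d",
          ncol(p$W_i), hid + length(x_t))
  }
  sp <- stack_lstm_params(p)
  Z <- rbind(matrix(prev$h, hid, 1L), matrix(x_t, ncol = 1L))
  A <- sp$Ws %*% Z + sp$bs
  i_g <- sigmoid(A[seq_len(hid), 1L])
  f_g <- sigmoid(A[hid + seq_len(hid), 1L])
  o_g <- sigmoid(A[2L * hid + seq_len(hid), 1L])
  g_g <- tanh(A[3L * hid + seq_len(hid), 1L])
  c_t <- f_g * prev$c + i_g * g_g
  list(h = o_g * tanh(c_t), c = c_t)
}

#' Bidirectional LSTM over a series
#'
#' Runs a forward pass over `t = 1..T` and an independent pass over the
#' reversed series (both from zero-initialised states) and merges the two
#' hidden sequences by elementwise sum.
#'
#' @param X numeric `T x D` series matrix.
#' @param p_fwd,p_bwd per-direction parameter lists as in [lstm_step()]
#'   (both directions share one hidden size).
#' @return numeric `T x hidden` matrix of merged hidden states.
#' @export
bilstm <- function(X, p_fwd, p_bwd) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (nrow(X) < 1L) stopf("bilstm: empty series")
  hid <- nrow(p_fwd$W_i)
  sf <- stack_lstm_params(p_fwd); sb <- stack_lstm_params(p_bwd)
  Xa <- array(X, c(nrow(X), ncol(X), 1L))
  fw <- lstm_seq_forward(Xa, sf$Ws, sf$bs, hid)
  bw <- lstm_seq_forward(Xa[rev(seq_len(nrow(X))), , , drop = FALSE], sb$Ws, sb$bs, hid)
  T_len <- nrow(X)
  out <- matrix(0, T_len, hid)
  for (t in seq_len(T_len)) {
    out[t, ] <- fw$Hseq[t, , 1L] + bw$Hseq[T_len + 1L - t, , 1L]
  }
  out
}

# Batched series branch: z-score -> BiLSTM -> temporal pooling -> linear.
series_forward_batch <- function(X, p, cfg, norm = NULL) {
  d <- dim(X); T_len <- d[1L]; D <- d[2L]; B <- d[3L]
  if (D != cfg$series$channels) {
    stopf("encode_series: series has %d channels, configured %d", D, cfg$series$channels)
  }
  if (!is.null(norm)) {
    X <- sweep(X, 2L, norm$mean, "-")
    X <- sweep(X, 2L, norm$sd, "/")
  }
  hid <- cfg$series$hidden
  fw <- lstm_seq_forward(X, p[["series.fwd.W"]], p[["series.fwd.b"]], hid)
  fw$Ws <- p[["series.fwd.W"]]
  Xr <- X[rev(seq_len(T_len)), , , drop = FALSE]
  bw <- lstm_seq_forward(Xr, p[["series.bwd.W"]], p[["series.bwd.b"]], hid)
  bw$Ws <- p[["series.bwd.W"]]
  merged <- fw$Hseq + bw$Hseq[rev(seq_len(T_len)), , , drop = FALSE]
  pooled <- if (cfg$series$pooling == "mean") {
    matrix(colMeans(matrix(merged, T_len, hid * B)), hid, B)
  } else {
    matrix(merged[T_len, , ], hid, B)
  }
  H <- p[["series.proj.W"]] %*% pooled + p[["series.proj.b"]]
  list(H = H, fw = fw, bw = bw, pooled = pooled, T_len = T_len)
}

series_backward_batch <- function(dH, fwd, p, cfg) {
  g <- list()
  g[["series.proj.W"]] <- tcrossprod(dH, fwd$pooled)
  g[["series.proj.b"]] <- rowSums(dH)
  dPooled <- crossprod(p[["series.proj.W"]], dH)
  hid <- cfg$series$hidden; T_len <- fwd$T_len; B <- ncol(dH)
  dMerged <- array(0, c(T_len, hid, B))
  if (cfg$series$pooling == "mean") {
    for (t in seq_len(T_len)) dMerged[t, , ] <- dPooled / T_len
  } else {
    dMerged[T_len, , ] <- dPooled
  }
  bf <- lstm_seq_backward(dMerged, fwd$fw)
  bb <- lstm_seq_backward(dMerged[rev(seq_len(T_len)), , , drop = FALSE], fwd$bw)
  g[["series.fwd.W"]] <- bf$dWs; g[["series.fwd.b"]] <- bf$dbs
  g[["series.bwd.W"]] <- bb$dWs; g[["series.bwd.b"]] <- bb$dbs
  g
}

#' Encode a physiological series into the common feature space
#'
#' Bi-LSTM over the (optionally z-scored) series, temporal pooling of the
#' merged hidden sequence (arithmetic mean by default, last step via
#' config), then a linear map to `d_model`.
#'
#' @param X numeric `T x D` series matrix with `D` matching the configured
#'   channel count.
#' @param params flat named parameter list (see [init_parameters()]).
#' @param config a [model_config()].
#' @param norm optional list with per-channel `mean` and `sd` (training-set
#'   statistics) used to z-score the input.
#' @return numeric vector of length `config$d_model` (the series feature
#'   H_n).
#' @export
encode_series <- function(X, params, config = model_config(), norm = NULL) {
  Xa <- array(as.matrix(X), c(nrow(X), ncol(X), 1L))
  as.numeric(series_forward_batch(Xa, params, config, norm)$H)
}
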