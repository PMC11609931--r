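# Self-attention text encoder.
#
# Pipeline: embedding lookup + sinusoidal positional encoding -> one
# multi-head self-attention block with a residual connection -> mean over
# token positions. Attention scores are scaled dot products,
# E_ij = (Q_i . K_j) / sqrt(d_k) by default (the `dk` score_scale divides
# by d_k instead); weights are a row-wise stable softmax; per-head outputs
# are concatenated along the feature axis and mixed by W_O.
#
# The multi-head forward/backward pair below is shared with the fusion
# head, which applies the same block to the 3-token modality sequence.

#' Sinusoidal positional encoding matrix
#'
#' Row `t` (0-based position) has `sin(t / 10000^(2k/d))` in even and
#' `cos(t / 10000^(2k/d))` in odd dimensions (1-based columns 1, 2, ...),
#' so position 0 encodes as the alternating 0/1 pattern.
#'
#' @param n number of positions.
#' @param d_model encoding width.
#' @return `n x d_model` matrix.
#' @export
positional_encoding <- function(n, d_model) {
  if (n == 0L) return(matrix(0, 0L, d_model))
  pos <- seq_len(n) - 1L
  P <- matrix(0, n, d_model)
  for (k in seq_len(ceiling(d_model / 2))) {
    freq <- 1 / 10000^((2 * (k - 1)) / d_model)
    P[, 2L * k - 1L] <- sin(pos * freq)
    if (2L * k <= d_model) P[, 2L * k] <- cos(pos * freq)
  }
  P
}

#' Embed tokens and add positional encoding
#'
#' @param tokens integer vector of 0-based token ids.
#' @param params flat named parameter list containing `text.emb`
#'   (`vocab x d_model`).
#' @param use_positional add the sinusoidal positional encoding?
#' @return `n x d_model` matrix (empty matrix for an empty sequence).
#' @export
embed_and_position <- function(tokens, params, use_positional = TRUE) {
  emb <- params[["text.emb"]]
  d_model <- ncol(emb)
  if (length(tokens) == 0L) return(matrix(0, 0L, d_model))
  bad <- which(tokens < 0L | tokens >= nrow(emb))
  if (length(bad)) {
    stopf("embed_and_position: token id %d at position %d outside vocabulary [0, %d)",
          tokens[bad[1L]], bad[1L], nrow(emb))
  }
  X <- emb[tokens + 1L, , drop = FALSE]
  if (use_positional) X <- X + positional_encoding(length(tokens), d_model)
  X
}

#' Scaled dot-product attention scores
#'
#' `E[i, j] = (Q_i . K_j) / s` where `s = sqrt(d_k)` (default) or `d_k`.
#'
#' @param Qm,Km `n x d_k` query and key matrices.
#' @param score_scale `"sqrt_dk"` or `"dk"`.
#' @return `n x n` score matrix.
#' @export
attention_scores <- function(Qm, Km, score_scale = "sqrt_dk") {
  if (ncol(Qm) != ncol(Km)) {
    stopf("attention_scores: query width %d != key width %d", ncol(Qm), ncol(Km))
  }
  dk <- ncol(Qm)
  s <- if (score_scale == "dk") dk else sqrt(dk)
  tcrossprod(Qm, Km) / s
}

#' Normalise attention scores to weights
#'
#' Row-wise softmax with max subtraction for numerical stability; each row
#' is non-negative and sums to 1.
#'
#' @param E finite numeric score matrix.
#' @return weight matrix of the same shape.
#' @export
attention_weights <- function(E) {
  if (any(!is.finite(E))) stopf("attention_weights: non-finite attention score")
  softmax_rows(E)
}

#' Attention-weighted combination of value rows
#'
#' `SA_i = sum_j A[i, j] V_j`; each output row is a convex combination of
#' the value rows.
#'
#' @param A `n x n` attention weight matrix.
#' @param Vm `n x d` value matrix.
#' @return `n x d` matrix.
#' @export
attention_output <- function(A, Vm) {
  if (ncol(A) != nrow(Vm)) {
    stopf("attention_output: weights have %d columns but %d value rows",
          ncol(A), nrow(Vm))
  }
  A %*% Vm
}

# Shared multi-head self-attention core. p: list(Wq, Wk, Wv, Wo) each
# d_model x d_model with heads as contiguous column blocks of width d_k.
mha_forward <- function(X, p, heads, score_scale = "sqrt_dk") {
  d_model <- ncol(X)
  if (d_model %% heads != 0L) {
    stopf("multi_head: head count %d does not divide d_model %d", heads, d_model)
  }
  dk <- d_model %/% heads
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  Z <- matrix(0, nrow(X), d_model)
  Alist <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    E <- attention_scores(Q[, idx, drop = FALSE], K[, idx, drop = FALSE], score_scale)
    A <- attention_weights(E)
    Alist[[h]] <- A
    Z[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- Z %*% p$Wo
  list(out = out, X = X, Q = Q, K = K, V = V, Z = Z, A = Alist,
       heads = heads, dk = dk, score_scale = score_scale)
}

mha_backward <- function(dOut, cache, p) {
  heads <- cache$heads; dk <- cache$dk
  scale <- if (cache$score_scale == "dk") dk else sqrt(dk)
  dWo <- crossprod(cache$Z, dOut)
  dZ <- tcrossprod(dOut, p$Wo)
  dQ <- matrix(0, nrow(cache$X), ncol(cache$X))
  dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    A <- cache$A[[h]]
    dOh <- dZ[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dE <- A * (dA - rowSums(A * dA))
    dQ[, idx] <- dE %*% cache$K[, idx, drop = FALSE] / scale
    dK[, idx] <- crossprod(dE, cache$Q[, idx, drop = FALSE]) / scale
  }
  dX <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dX = dX, dWq = crossprod(cache$X, dQ), dWk = crossprod(cache$X, dK),
       dWv = crossprod(cache$X, dV), dWo = dWo)
}

#' Multi-head self-attention over a position-encoded sequence
#'
#' Per head h: `SA^h = softmax(Q_h K_h' / sqrt(d_k)) V_h` with
#' `Q_h = X W_Q^h` etc.; the head outputs are concatenated along the
#' feature axis and mixed by `W_O`, so the output width equals `d_model`.
#'
#' @param Xp `n x d_model` input matrix.
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (`d_model x d_model`,
#'   heads as contiguous column blocks).
#' @param heads head count (must divide `d_model`).
#' @param score_scale `"sqrt_dk"` or `"dk"`.
#' @return `n x d_model` matrix.
#' @export
multi_head <- function(Xp, params, heads = 4L, score_scale = "sqrt_dk") {
  mha_forward(Xp, params, heads, score_scale)$out
}

text_mha_params <- function(p) {
  list(Wq = p[["text.att.Wq"]], Wk = p[["text.att.Wk"]],
       Wv = p[["text.att.Wv"]], Wo = p[["text.att.Wo"]])
}

# Per-sample text branch with cache (batch loops over samples since token
# sequences have varying length).
text_forward_one <- function(tokens, p, cfg) {
  d_model <- cfg$d_model
  if (length(tokens) == 0L) {
    return(list(H = numeric(d_model), empty = TRUE))
  }
  Xp <- embed_and_position(tokens, p, cfg$text$use_positional)
  att <- mha_forward(Xp, text_mha_params(p), cfg$text$heads, cfg$text$score_scale)
  R <- Xp + att$out
  list(H = colMeans(R), att = att, Xp = Xp, tokens = tokens, n = length(tokens),
       empty = FALSE)
}

text_backward_one <- function(dH, fwd, p, g) {
  if (isTRUE(fwd$empty)) return(g)
  n <- fwd$n
  dR <- matrix(rep(dH / n, each = n), n, length(dH))
  bk <- mha_backward(dR, fwd$att, text_mha_params(p))
  dXp <- dR + bk$dX
  g[["text.att.Wq"]] <- g[["text.att.Wq"]] + bk$dWq
  g[["text.att.Wk"]] <- g[["text.att.Wk"]] + bk$dWk
  g[["text.att.Wv"]] <- g[["text.att.Wv"]] + bk$dWv
  g[["text.att.Wo"]] <- g[["text.att.Wo"]] + bk$dWo
  ids <- fwd$tokens + 1L
  for (u in unique(ids)) {
    rows <- which(ids == u)
    g[["text.emb"]][u, ] <- g[["text.emb"]][u, ] +
      colSums(dXp[rows, , drop = FALSE])
  }
  g
}

#' Encode a token sequence into the common feature space
#'
#' Embedding + positional encoding, one multi-head self-attention block
#' with a residual connection, then the mean over token positions. An
#' empty sequence encodes to the zero vector.
#'
#' @param tokens integer vector of 0-based token ids.
#' @param params flat named parameter list (see [init_parameters()]).
#' @param config a [model_config()].
#' @return numeric vector of length `config$d_model` (the text feature
#'   H_t).
#' @export
encode_text <- function(tokens, params, config = model_config()) {
  text_forward_one(as.integer(tokens), params, config)$H
}
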