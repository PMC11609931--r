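# Shared builders for miniature configurations and random instances.

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(d_model = 8L,
         image = list(size = 16L, channels = 1L, blocks = c(2L, 3L), kernel = 3L),
         series = list(channels = 2L, hidden = 3L),
         text = list(vocab = 25L, heads = 2L),
         fusion = list(heads = 2L)),
    list(...))
  do.call(model_config, args)
}

tiny_generator_config <- function(...) {
  args <- utils::modifyList(
    list(n_cases = 4L, n_controls = 4L, image_size = 16L,
         series_length = 5L, series_channels = 2L, vocab_size = 25L),
    list(...))
  do.call(generator_config, args)
}

# random LSTM parameter set in the separate-matrix form of lstm_step()
random_lstm_params <- function(hidden, input, seed = 1L) {
  withr::with_seed(seed, {
    r <- function() matrix(rnorm(hidden * (hidden + input), sd = 0.5),
                           hidden, hidden + input)
    list(W_i = r(), W_f = r(), W_o = r(), W_c = r(),
         b_i = rnorm(hidden, sd = 0.2), b_f = rnorm(hidden, sd = 0.2),
         b_o = rnorm(hidden, sd = 0.2), b_c = rnorm(hidden, sd = 0.2))
  })
}

zero_lstm_params <- function(hidden, input) {
  z <- matrix(0, hidden, hidden + input)
  list(W_i = z, W_f = z, W_o = z, W_c = z,
       b_i = numeric(hidden), b_f = numeric(hidden),
       b_o = numeric(hidden), b_c = numeric(hidden))
}

# brute-force quadruple-loop valid cross-correlation oracle
conv2d_oracle <- function(image, W, b = NULL) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (is.matrix(W)) dim(W) <- c(dim(W), 1L, 1L)
  dW <- dim(W); M <- dW[1]; N <- dW[2]; C <- dW[3]; F_ <- dW[4]
  if (is.null(b)) b <- numeric(F_)
  H <- dim(image)[1]; Wd <- dim(image)[2]
  out <- array(0, c(H - M + 1, Wd - N + 1, F_))
  for (f in seq_len(F_)) for (x in seq_len(H - M + 1)) for (y in seq_len(Wd - N + 1)) {
    acc <- 0
    for (i in seq_len(M)) for (j in seq_len(N)) for (c in seq_len(C)) {
      acc <- acc + image[x + i - 1, y + j - 1, c] * W[i, j, c, f]
    }
    out[x, y, f] <- acc + b[f]
  }
  out
}

# window-scan max pooling oracle
maxpool2_oracle <- function(fm) {
  if (is.matrix(fm)) dim(fm) <- c(dim(fm), 1L)
  d <- dim(fm)
  out <- array(0, c(d[1] %/% 2, d[2] %/% 2, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(d[1] %/% 2)) for (j in seq_len(d[2] %/% 2)) {
    out[i, j, c] <- max(fm[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  }
  out
}

# all-pairs counting AUC oracle (ties counted 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# central finite-difference gradient of f at theta (selected indices)
numeric_gradient <- function(f, theta, idx = seq_along(theta), eps = 1e-5) {
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    tp <- theta; tp[idx[k]] <- tp[idx[k]] + eps
    tm <- theta; tm[idx[k]] <- tm[idx[k]] - eps
    g[k] <- (f(tp) - f(tm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
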