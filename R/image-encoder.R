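# Convolutional image encoder.
#
# The stack is `n_blocks x [valid cross-correlation -> ReLU -> 2x2 max
# pool]`, followed by global average pooling over spatial positions and a
# linear map to the common feature width d_model. Convolution is the
# unflipped-kernel (cross-correlation) convention with valid padding and
# stride 1; output size (H - M + 1) x (W - N + 1).
#
# Internally images travel as 4-D arrays in (H, W, B, C) layout so a whole
# mini-batch shares one im2col + matrix multiply per layer with no
# transposes; the exported single-sample operations are thin wrappers over
# the batched kernels.

as_hwbc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  else if (length(dim(x)) == 3L) x <- array(x, c(dim(x)[1:2], 1L, dim(x)[3L]))
  x
}

conv_forward_batch <- function(X, W, b) {
  dW <- dim(W); M <- dW[1L]; N <- dW[2L]; C_in <- dW[3L]; F_out <- dW[4L]
  d <- dim(X)
  if (d[4L] != C_in) stopf("conv2d: input has %d channels, kernel expects %d", d[4L], C_in)
  if (M > d[1L] || N > d[2L]) {
    stopf("conv2d: kernel (%dx%d) larger than image (%dx%d)", M, N, d[1L], d[2L])
  }
  Ho <- d[1L] - M + 1L; Wo <- d[2L] - N + 1L; B <- d[3L]
  cols <- im2col_cpp(X, as.integer(d), M, N)
  out <- cols %*% matrix(W, ncol = F_out)
  out <- sweep(out, 2L, b, "+")
  dim(out) <- c(Ho, Wo, B, F_out)
  list(out = out, cols = cols, in_dim = d)
}

conv_backward_batch <- function(dOut, cache, W, need_dx = TRUE) {
  dW_dim <- dim(W); M <- dW_dim[1L]; N <- dW_dim[2L]; C <- dW_dim[3L]; F_out <- dW_dim[4L]
  d <- cache$in_dim
  Ho <- d[1L] - M + 1L; Wo <- d[2L] - N + 1L; B <- d[3L]
  dOut_m <- matrix(dOut, Ho * Wo * B, F_out)
  dW <- array(crossprod(cache$cols, dOut_m), dim = dW_dim)
  db <- colSums(dOut_m)
  dX <- NULL
  if (need_dx) {
    dcols <- tcrossprod(dOut_m, matrix(W, ncol = F_out))
    dX <- col2im_cpp(dcols, as.integer(d), M, N)
  }
  list(dX = dX, dW = dW, db = db)
}

maxpool_forward_batch <- function(X) {
  d <- dim(X)
  if (d[1L] < 2L || d[2L] < 2L) stopf("maxpool2: spatial dimensions must be >= 2")
  res <- maxpool_fwd_cpp(X, as.integer(d))
  list(out = res$out, which = res$which, in_dim = d)
}

maxpool_backward_batch <- function(dOut, cache) {
  maxpool_bwd_cpp(dOut, cache$which, as.integer(cache$in_dim))
}

#' Valid 2-D cross-correlation of an image with a kernel bank
#'
#' Slides the unflipped kernel over the image (stride 1, no padding), sums
#' over input channels and adds the bias, so the output at (x, y) is
#' `sum_{i,j,c} I[x+i-1, y+j-1, c] * K[i, j, c, f] + b[f]`. Output spatial
#' size is (H - M + 1) x (W - N + 1).
#'
#' @param image numeric `H x W` matrix or `H x W x C` array.
#' @param kernel list with `weights` (`M x N x C_in x C_out` array; a plain
#'   `M x N` matrix is promoted to one input and one output channel) and
#'   optional `bias` (length `C_out`, default 0).
#' @return `H' x W' x C_out` feature-map array.
#' @export
conv2d <- function(image, kernel) {
  W <- kernel$weights
  if (is.matrix(W)) dim(W) <- c(dim(W), 1L, 1L)
  b <- kernel$bias %||% numeric(dim(W)[4L])
  out <- conv_forward_batch(as_hwbc(image), W, b)$out
  array(out, dim(out)[c(1L, 2L, 4L)])
}

#' Rectified linear activation
#'
#' Elementwise `max(0, x)`; shape preserved.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' 2x2 max pooling with stride 2
#'
#' Non-overlapping 2x2 windows; a trailing odd row/column is dropped. Each
#' output value is the maximum of its window.
#'
#' @param fm feature map: `H x W` matrix or `H x W x C` array with spatial
#'   dimensions >= 2.
#' @return pooled map of halved (floor) spatial size, same channel count.
#' @export
maxpool2 <- function(fm) {
  was_mat <- is.matrix(fm)
  out <- maxpool_forward_batch(as_hwbc(fm))$out
  if (was_mat) matrix(out, dim(out)[1L], dim(out)[2L]) else array(out, dim(out)[c(1L, 2L, 4L)])
}

# Full batched image branch: conv blocks -> GAP -> linear to d_model.
# X in (H, W, B, C) layout; returns H_i as a (d_model x B) matrix.
image_forward_batch <- function(X, p, cfg) {
  d <- dim(X)
  if (d[1L] != cfg$image$size || d[4L] != cfg$image$channels) {
    stopf("encode_image: input %dx%dx%d does not match configured %dx%dx%d",
          d[1L], d[2L], d[4L], cfg$image$size, cfg$image$size, cfg$image$channels)
  }
  caches <- list()
  for (k in seq_along(cfg$image$blocks)) {
    cv <- conv_forward_batch(X, p[[paste0("image.conv", k, ".W")]],
                             p[[paste0("image.conv", k, ".b")]])
    a <- relu(cv$out)
    mp <- maxpool_forward_batch(a)
    caches[[k]] <- list(conv = cv, pre_relu = cv$out, pool = mp)
    X <- mp$out
  }
  dd <- dim(X)  # (Ho, Wo, B, F)
  feat <- t(matrix(colMeans(matrix(X, dd[1L] * dd[2L], dd[3L] * dd[4L])), dd[3L], dd[4L]))
  H <- p[["image.proj.W"]] %*% feat + p[["image.proj.b"]]
  list(H = H, caches = caches, feat = feat, gap_dim = dd)
}

image_backward_batch <- function(dH, fwd, p, cfg) {
  g <- list()
  g[["image.proj.W"]] <- tcrossprod(dH, fwd$feat)
  g[["image.proj.b"]] <- rowSums(dH)
  dFeat <- crossprod(p[["image.proj.W"]], dH)  # (F x B)^T -> F x B
  dd <- fwd$gap_dim
  # spread the GAP gradient uniformly over spatial positions; dFeat is F x B
  # but the array layout is (Ho, Wo, B, F), so transpose to B x F first
  dX <- array(rep(as.vector(t(dFeat)), each = dd[1L] * dd[2L]) / (dd[1L] * dd[2L]), dd)
  for (k in rev(seq_along(cfg$image$blocks))) {
    cache <- fwd$caches[[k]]
    dA <- maxpool_backward_batch(dX, cache$pool)
    dA <- dA * (cache$pre_relu > 0)
    bk <- conv_backward_batch(dA, cache$conv, p[[paste0("image.conv", k, ".W")]],
                              need_dx = k > 1L)
    g[[paste0("image.conv", k, ".W")]] <- bk$dW
    g[[paste0("image.conv", k, ".b")]] <- bk$db
    dX <- bk$dX
  }
  g
}

#' Encode an image into the common feature space
#'
#' Applies the configured convolutional stack (default two blocks of
#' cross-correlation, ReLU and 2x2 max pooling), global average pooling
#' over spatial positions, and a linear map to `d_model`.
#'
#' @param image `H x W` matrix or `H x W x C` array matching the configured
#'   input shape.
#' @param params flat named parameter list (see [init_parameters()]).
#' @param config a [model_config()].
#' @return numeric vector of length `config$d_model` (the image feature
#'   H_i).
#' @export
encode_image <- function(image, params, config = model_config()) {
  as.numeric(image_forward_batch(as_hwbc(image), params, config)$H)
}
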