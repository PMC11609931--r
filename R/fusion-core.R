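# Attention-weighted modality fusion head.
#
# Given the modality features H_m (m over the instantiated modalities):
#   alpha_m = E(W_m H_m)          projection, E = tanh by default
#   beta    = MHSA([alpha_m])     cross-modality self-attention (rows beta_m)
#   E_m     = s . beta_m          learned scoring vector
#   w       = softmax(E)          fusion weights on the simplex
#   M       = sum_m w_m beta_m    fused representation
#   Yhat    = softmax(lambda M + b)
# With config `fuse_input = "alpha"` the scoring/fusion steps read the
# projected tokens alpha directly instead of the attention-mixed beta.

#' Project modality features into fusion tokens
#'
#' `alpha_m = E(W_m H_m)` with `E` an elementwise nonlinearity (tanh by
#' default, identity via `nonlinearity = "identity"`).
#'
#' @param H_i,H_n,H_t modality feature vectors of equal length (image,
#'   series, text).
#' @param proj list with square matrices `W_i`, `W_n`, `W_t` and optional
#'   `nonlinearity` (`"tanh"` or `"identity"`).
#' @return list with vectors `alpha_i`, `alpha_n`, `alpha_t`.
#' @export
project_modalities <- function(H_i, H_n, H_t, proj) {
  nl <- proj$nonlinearity %||% "tanh"
  one <- function(W, H) {
    if (ncol(W) != length(H)) {
      stopf("project_modalities: feature length %d does not match projection width %d",
            length(H), ncol(W))
    }
    z <- as.numeric(W %*% H)
    if (nl == "tanh") tanh(z) else z
  }
  list(alpha_i = one(proj$W_i, H_i),
       alpha_n = one(proj$W_n, H_n),
       alpha_t = one(proj$W_t, H_t))
}

#' Cross-modality self-attention over the three fusion tokens
#'
#' Stacks the projected modality vectors as a 3-token sequence and applies
#' multi-head self-attention (same machinery as the text encoder).
#'
#' @param alpha_i,alpha_n,alpha_t projected modality vectors (length
#'   `d_model`).
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` and optional `heads`
#'   (default 1) and `score_scale`.
#' @return `3 x d_model` matrix whose rows are the fused tokens beta.
#' @export
fuse_attention <- function(alpha_i, alpha_n, alpha_t, params) {
  A <- rbind(alpha_i, alpha_n, alpha_t)
  rownames(A) <- NULL
  mha_forward(A, params, params$heads %||% 1L,
              params$score_scale %||% "sqrt_dk")$out
}

#' Softmax fusion weights from modality scores
#'
#' `w_m = exp(E_m) / sum_j exp(E_j)`; the output lies on the simplex and is
#' invariant to adding a constant to all scores.
#'
#' @param E finite numeric score vector (one score per modality).
#' @return weight vector of the same length.
#' @export
fusion_weights <- function(E) {
  if (any(!is.finite(E))) stopf("fusion_weights: non-finite score")
  softmax_vec(E)
}

#' Weighted fusion of modality tokens
#'
#' `M = sum_m w_m beta_m`.
#'
#' @param beta `k x d_model` matrix of fused tokens (rows).
#' @param w simplex weight vector of length `k`.
#' @return fused vector of length `d_model`.
#' @export
weighted_fuse <- function(beta, w) {
  if (length(w) != nrow(beta)) stopf("weighted_fuse: %d weights for %d tokens",
                                     length(w), nrow(beta))
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6) {
    stopf("weighted_fuse: weights must be non-negative and sum to 1")
  }
  as.numeric(crossprod(beta, w))
}

#' Softmax classifier over the fused representation
#'
#' `Yhat = softmax(lambda M + b)`.
#'
#' @param M fused feature vector.
#' @param cls list with `W` (`K x d_model`) and `b` (length `K`).
#' @return probability vector on the K-simplex.
#' @export
classify <- function(M, cls) {
  if (ncol(cls$W) != length(M)) {
    stopf("classify: feature length %d does not match classifier width %d",
          length(M), ncol(cls$W))
  }
  softmax_vec(as.numeric(cls$W %*% M) + cls$b)
}

#' Cross-entropy loss against a one-hot label
#'
#' `l = -sum_k Y_k log(Yhat_k)` with probabilities clamped at 1e-12 before
#' the logarithm.
#'
#' @param yhat predicted probability vector.
#' @param y one-hot label vector of the same length.
#' @return scalar loss.
#' @export
cross_entropy <- function(yhat, y) {
  if (!all(y %in% c(0, 1)) || sum(y) != 1) {
    stopf("cross_entropy: label must be one-hot")
  }
  -sum(y * log(pmax(yhat, 1e-12)))
}

fusion_mha_params <- function(p) {
  list(Wq = p[["fusion.att.Wq"]], Wk = p[["fusion.att.Wk"]],
       Wv = p[["fusion.att.Wv"]], Wo = p[["fusion.att.Wo"]])
}

# Fusion head for one sample. H: list of modality feature vectors keyed by
# modality name, in cfg$modalities order.
fusion_forward_one <- function(H, p, cfg) {
  mods <- cfg$modalities
  nl <- cfg$fusion$projection_nonlinearity
  Z <- lapply(mods, function(m) as.numeric(p[[paste0("fusion.proj.", m)]] %*% H[[m]]))
  alpha <- if (nl == "tanh") lapply(Z, tanh) else Z
  A <- do.call(rbind, alpha)
  if (cfg$fusion$fuse_input == "mf") {
    att <- mha_forward(A, fusion_mha_params(p), cfg$fusion$heads, cfg$text$score_scale)
    beta <- att$out
  } else {
    att <- NULL
    beta <- A
  }
  E <- as.numeric(beta %*% p[["fusion.score"]])
  w <- softmax_vec(E)
  M <- as.numeric(crossprod(beta, w))
  logits <- as.numeric(p[["fusion.cls.W"]] %*% M) + p[["fusion.cls.b"]]
  probs <- softmax_vec(logits)
  list(probs = probs, logits = logits, M = M, w = w, E = E, beta = beta,
       alpha = alpha, A = A, att = att, H = H)
}

# Backward for one sample given dLogits; accumulates into g and returns
# list(g = g, dH = list per modality).
fusion_backward_one <- function(dLogits, fwd, p, cfg, g) {
  mods <- cfg$modalities
  g[["fusion.cls.W"]] <- g[["fusion.cls.W"]] + outer(dLogits, fwd$M)
  g[["fusion.cls.b"]] <- g[["fusion.cls.b"]] + dLogits
  dM <- as.numeric(crossprod(p[["fusion.cls.W"]], dLogits))
  dBeta <- fwd$w %o% dM
  dw <- as.numeric(fwd$beta %*% dM)
  dE <- fwd$w * (dw - sum(fwd$w * dw))
  dBeta <- dBeta + dE %o% p[["fusion.score"]]
  g[["fusion.score"]] <- g[["fusion.score"]] + as.numeric(crossprod(fwd$beta, dE))
  if (cfg$fusion$fuse_input == "mf") {
    bk <- mha_backward(dBeta, fwd$att, fusion_mha_params(p))
    dA <- bk$dX
    for (w_ in c("Wq", "Wk", "Wv", "Wo")) {
      nm <- paste0("fusion.att.", w_)
      g[[nm]] <- g[[nm]] + bk[[paste0("d", w_)]]
    }
  } else {
    dA <- dBeta
  }
  dH <- list()
  for (k in seq_along(mods)) {
    m <- mods[k]
    dz <- dA[k, ]
    if (cfg$fusion$projection_nonlinearity == "tanh") {
      dz <- dz * (1 - fwd$alpha[[k]]^2)
    }
    nm <- paste0("fusion.proj.", m)
    g[[nm]] <- g[[nm]] + outer(dz, fwd$H[[m]])
    dH[[m]] <- as.numeric(crossprod(p[[nm]], dz))
  }
  list(g = g, dH = dH)
}

# ---- full-model batched forward/backward -------------------------------

check_sample_modalities <- function(s, cfg) {
  for (m in cfg$modalities) {
    field <- switch(m, image = "image", series = "series", text = "tokens")
    if (is.null(s[[field]])) {
      stopf("sample %s is missing the '%s' modality required by the model",
            s$sample_id %||% "?", m)
    }
  }
}

model_forward_batch <- function(batch, p, cfg, norm = NULL) {
  B <- length(batch)
  for (s in batch) check_sample_modalities(s, cfg)
  Hmat <- list()
  img_fwd <- ser_fwd <- NULL
  txt_fwd <- NULL
  if ("image" %in% cfg$modalities) {
    S <- cfg$image$size; C <- cfg$image$channels
    X <- array(0, c(S, S, B, C))
    for (b in seq_len(B)) X[, , b, ] <- batch[[b]]$image
    img_fwd <- image_forward_batch(X, p, cfg)
    Hmat$image <- img_fwd$H
  }
  if ("series" %in% cfg$modalities) {
    T_len <- nrow(batch[[1L]]$series); D <- cfg$series$channels
    X <- array(0, c(T_len, D, B))
    for (b in seq_len(B)) X[, , b] <- batch[[b]]$series
    ser_fwd <- series_forward_batch(X, p, cfg, norm)
    Hmat$series <- ser_fwd$H
  }
  if ("text" %in% cfg$modalities) {
    txt_fwd <- lapply(batch, function(s) text_forward_one(as.integer(s$tokens), p, cfg))
    Hmat$text <- vapply(txt_fwd, `[[`, numeric(cfg$d_model), "H")
    if (is.null(dim(Hmat$text))) Hmat$text <- matrix(Hmat$text, cfg$d_model, B)
  }
  fus <- vector("list", B)
  probs <- matrix(0, cfg$n_classes, B)
  for (b in seq_len(B)) {
    H <- lapply(Hmat[cfg$modalities], function(Mx) Mx[, b])
    names(H) <- cfg$modalities
    fus[[b]] <- fusion_forward_one(H, p, cfg)
    probs[, b] <- fus[[b]]$probs
  }
  list(probs = probs, fus = fus, img_fwd = img_fwd, ser_fwd = ser_fwd,
       txt_fwd = txt_fwd, B = B)
}

# labels: integer vector in 0..K-1. Returns list(loss, grads).
model_backward_batch <- function(fwd, labels, p, cfg) {
  B <- fwd$B
  K <- cfg$n_classes
  Y <- matrix(0, K, B)
  Y[cbind(labels + 1L, seq_len(B))] <- 1
  loss <- mean(-log(pmax(fwd$probs[cbind(labels + 1L, seq_len(B))], 1e-12)))
  g <- zero_like(p)
  dH <- list()
  for (m in cfg$modalities) dH[[m]] <- matrix(0, cfg$d_model, B)
  for (b in seq_len(B)) {
    dLogits <- (fwd$probs[, b] - Y[, b]) / B
    res <- fusion_backward_one(dLogits, fwd$fus[[b]], p, cfg, g)
    g <- res$g
    for (m in cfg$modalities) dH[[m]][, b] <- res$dH[[m]]
  }
  if ("image" %in% cfg$modalities) {
    g <- add_grads(g, image_backward_batch(dH$image, fwd$img_fwd, p, cfg))
  }
  if ("series" %in% cfg$modalities) {
    g <- add_grads(g, series_backward_batch(dH$series, fwd$ser_fwd, p, cfg))
  }
  if ("text" %in% cfg$modalities) {
    for (b in seq_len(B)) {
      g <- text_backward_one(dH$text[, b], fwd$txt_fwd[[b]], p, g)
    }
  }
  list(loss = loss, grads = g)
}

#' Predict class probabilities for one sample
#'
#' Runs the full forward pass (modality encoders, projections,
#' cross-modality attention, fusion weights, weighted fusion, softmax
#' classifier). The label is `argmax_k Yhat_k` with ties broken toward the
#' lower class index. Deterministic given (sample, parameters).
#'
#' @param sample list with the modality fields required by the config
#'   (`image`, `series`, `tokens`).
#' @param params flat named parameter list.
#' @param config a [model_config()].
#' @param norm optional series normalisation statistics.
#' @return list with `probs` (K-vector), `label` (0-based predicted
#'   class), and `fusion_weights`.
#' @export
predict_sample <- function(sample, params, config = model_config(), norm = NULL) {
  if (!is.null(sample$image) && is.matrix(sample$image)) {
    sample$image <- array(sample$image, c(dim(sample$image), 1L))
  }
  fwd <- model_forward_batch(list(sample), params, config, norm)
  probs <- fwd$probs[, 1L]
  list(probs = probs, label = which.max(probs) - 1L,
       fusion_weights = fwd$fus[[1L]]$w)
}
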