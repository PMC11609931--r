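# Training loop: mini-batch AdamW (decoupled weight decay) minimising the
# mean cross-entropy, with analytic gradients from the batched backward
# pass. Everything that consumes randomness (parameter init, shuffling)
# is driven by the train_config seed, so identical seeds give identical
# loss histories.

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(theta, grad, state, tc, decay_mask) {
  state$t <- state$t + 1L
  state$m <- tc$beta1 * state$m + (1 - tc$beta1) * grad
  state$v <- tc$beta2 * state$v + (1 - tc$beta2) * grad^2
  mhat <- state$m / (1 - tc$beta1^state$t)
  vhat <- state$v / (1 - tc$beta2^state$t)
  theta <- theta - tc$learning_rate * mhat / (sqrt(vhat) + tc$epsilon) -
    tc$learning_rate * tc$weight_decay * decay_mask * theta
  list(theta = theta, state = state)
}

series_norm_stats <- function(samples) {
  if (length(samples) == 0L || is.null(samples[[1L]]$series)) return(NULL)
  X <- do.call(rbind, lapply(samples, `[[`, "series"))
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ < 1e-8] <- 1
  list(mean = colMeans(X), sd = sd_)
}

#' Train the multimodal classifier
#'
#' Mini-batch AdamW on the mean cross-entropy over the training split.
#' Series channels are z-scored with statistics computed from the training
#' split only (stored in the fitted model and reused at prediction time).
#'
#' @param dataset list with `samples` and `manifest` as returned by
#'   [generate_dataset()] or [read_fixtures()]; rows with
#'   `split == "train"` are used.
#' @param config a [model_config()]; its `modalities` field selects which
#'   branches are instantiated.
#' @param tc a [train_config()].
#' @return object of class `ildfusion_model`: `params`, `config`, `norm`,
#'   `loss_history` (mean training loss per epoch), `tc`.
#' @export
train_model <- function(dataset, config = model_config(), tc = train_config()) {
  train_idx <- which(dataset$manifest$split == "train")
  samples <- dataset$samples[train_idx]
  if (length(samples) == 0L) stopf("train_model: empty training split")
  labels <- vapply(samples, `[[`, integer(1), "label")
  if (length(unique(labels)) < 2L) {
    stopf("train_model: training split contains a single class")
  }
  samples <- lapply(samples, function(s) {
    if (!is.null(s$image) && is.matrix(s$image)) {
      s$image <- array(s$image, c(dim(s$image), 1L))
    }
    s
  })
  norm <- if ("series" %in% config$modalities) series_norm_stats(samples) else NULL

  p <- init_parameters(config, seed = tc$rng_seed)
  fp <- flatten_params(p)
  theta <- fp$theta
  skeleton <- fp$skeleton
  # decoupled weight decay on weight arrays only, not biases
  decay_mask <- unlist(lapply(names(skeleton), function(nm) {
    rep(if (grepl("\\.b$", nm) || nm == "fusion.cls.b") 0 else 1,
        prod(skeleton[[nm]]))
  }))
  opt <- adamw_init(length(theta))
  n <- length(samples)
  loss_history <- numeric(tc$epochs)

  withr::with_seed(derive_seed(tc$rng_seed, 0L, 9L), {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq.int(1L, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, n)]
        batch <- samples[idx]
        p <- unflatten_params(theta, skeleton)
        fwd <- model_forward_batch(batch, p, config, norm)
        bwd <- model_backward_batch(fwd, labels[idx], p, config)
        batch_losses <- c(batch_losses, bwd$loss)
        if (tc$learning_rate > 0) {
          grad <- flatten_params(bwd$grads)$theta
          st <- adamw_step(theta, grad, opt, tc, decay_mask)
          theta <- st$theta; opt <- st$state
        }
      }
      loss_history[epoch] <- mean(batch_losses)
    }
  })

  structure(list(params = unflatten_params(theta, skeleton), config = config,
                 norm = norm, loss_history = loss_history, tc = tc),
            class = "ildfusion_model")
}

#' Predict with a fitted model
#'
#' @param object an `ildfusion_model`.
#' @param samples list of multimodal samples.
#' @param ... unused.
#' @return list with `probs` (`K x n` matrix), `labels` (0-based predicted
#'   classes), `scores` (probability of the positive class 1).
#' @export
predict.ildfusion_model <- function(object, samples, ...) {
  samples <- lapply(samples, function(s) {
    if (!is.null(s$image) && is.matrix(s$image)) {
      s$image <- array(s$image, c(dim(s$image), 1L))
    }
    s
  })
  probs <- matrix(0, object$config$n_classes, length(samples))
  for (b in seq_along(samples)) {
    probs[, b] <- model_forward_batch(samples[b], object$params, object$config,
                                      object$norm)$probs[, 1L]
  }
  labels <- apply(probs, 2L, which.max) - 1L
  list(probs = probs, labels = labels, scores = probs[2L, ])
}

#' Evaluate a fitted model on the test split
#'
#' @param model an `ildfusion_model`.
#' @param dataset list with `samples` and `manifest`; rows with
#'   `split == "test"` are used unless `split` says otherwise.
#' @param split which manifest split to evaluate (`"test"` default).
#' @return a [metric_report()].
#' @export
evaluate_model <- function(model, dataset, split = "test") {
  idx <- which(dataset$manifest$split == split)
  if (length(idx) == 0L) stopf("evaluate_model: empty '%s' split", split)
  samples <- dataset$samples[idx]
  truth <- vapply(samples, `[[`, integer(1), "label")
  pr <- predict(model, samples)
  metric_report(pr$scores, pr$labels, truth)
}
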