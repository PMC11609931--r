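# Model parameters are a FLAT named list of numeric arrays with a stable
# ordering (enumerable as theta). Names are dotted paths, e.g.
# "image.conv1.W", "fusion.cls.b". Only the branches named in
# config$modalities are instantiated, which is how modality ablation works.

#' Initialise model parameters
#'
#' Weights are drawn uniformly from +/- 1/sqrt(fan_in); biases start at 0
#' except the LSTM forget-gate bias, which starts at 1 (the usual device to
#' keep early cell states from being forgotten).
#'
#' @param config a [model_config()].
#' @param seed integer seed; identical config + seed give identical
#'   parameters.
#' @return flat named list of numeric arrays (theta).
#' @export
init_parameters <- function(config, seed = 1L) {
  withr::with_seed(seed, init_parameters_impl(config))
}

runif_fan <- function(dims, fan_in) {
  r <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -r, r), dim = dims)
}

init_parameters_impl <- function(cfg) {
  d <- cfg$d_model
  p <- list()
  if ("image" %in% cfg$modalities) {
    kk <- cfg$image$kernel
    c_in <- cfg$image$channels
    for (k in seq_along(cfg$image$blocks)) {
      c_out <- cfg$image$blocks[k]
      p[[paste0("image.conv", k, ".W")]] <- runif_fan(c(kk, kk, c_in, c_out),
                                                      kk * kk * c_in)
      p[[paste0("image.conv", k, ".b")]] <- numeric(c_out)
      c_in <- c_out
    }
    p[["image.proj.W"]] <- runif_fan(c(d, c_in), c_in)
    p[["image.proj.b"]] <- numeric(d)
  }
  if ("series" %in% cfg$modalities) {
    hid <- cfg$series$hidden; D <- cfg$series$channels
    for (dir in c("fwd", "bwd")) {
      p[[paste0("series.", dir, ".W")]] <- runif_fan(c(4L * hid, hid + D), hid + D)
      b <- numeric(4L * hid)
      b[hid + seq_len(hid)] <- 1  # forget gate
      p[[paste0("series.", dir, ".b")]] <- b
    }
    p[["series.proj.W"]] <- runif_fan(c(d, hid), hid)
    p[["series.proj.b"]] <- numeric(d)
  }
  if ("text" %in% cfg$modalities) {
    p[["text.emb"]] <- runif_fan(c(cfg$text$vocab, d), d)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0("text.att.", w)]] <- runif_fan(c(d, d), d)
    }
  }
  for (m in cfg$modalities) {
    p[[paste0("fusion.proj.", m)]] <- runif_fan(c(d, d), d)
  }
  for (w in c("Wq", "Wk", "Wv", "Wo")) {
    p[[paste0("fusion.att.", w)]] <- runif_fan(c(d, d), d)
  }
  p[["fusion.score"]] <- runif_fan(d, d)
  p[["fusion.cls.W"]] <- runif_fan(c(cfg$n_classes, d), d)
  p[["fusion.cls.b"]] <- numeric(cfg$n_classes)
  p
}

#' Flatten parameters to a single numeric vector
#'
#' @param p flat named list of arrays.
#' @return list with `theta` (numeric vector) and `skeleton` (per-array
#'   dims used by [unflatten_params()]).
#' @export
flatten_params <- function(p) {
  list(theta = unlist(p, use.names = FALSE),
       skeleton = lapply(p, function(a) dim(a) %||% length(a)))
}

#' Rebuild a parameter list from a flat vector
#'
#' @param theta numeric vector as produced by [flatten_params()].
#' @param skeleton the matching skeleton.
#' @return flat named list of arrays.
#' @export
unflatten_params <- function(theta, skeleton) {
  p <- vector("list", length(skeleton))
  names(p) <- names(skeleton)
  off <- 0L
  for (nm in names(skeleton)) {
    dims <- skeleton[[nm]]
    len <- prod(dims)
    v <- theta[off + seq_len(len)]
    p[[nm]] <- if (length(dims) > 1L) array(v, dims) else v
    off <- off + len
  }
  p
}

# Zero-filled gradient accumulator with the same shapes as p.
zero_like <- function(p) lapply(p, function(a) if (is.null(dim(a))) numeric(length(a)) else array(0, dim(a)))

add_grads <- function(g, h) {
  for (nm in names(h)) {
    g[[nm]] <- if (is.null(g[[nm]])) h[[nm]] else g[[nm]] + h[[nm]]
  }
  g
}
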