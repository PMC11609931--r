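#' Synthetic cohort generator configuration
#'
#' The defaults reproduce the study conditions the package is designed
#' around: a 40-case / 20-control cohort (2:1 class imbalance), a PaO2-like
#' physiological channel centred near 85 mmHg for ILD cases and 95 mmHg for
#' controls, and full-strength class signal in all three modalities.
#'
#' `pao2_sd` is the between-subject scatter (mmHg) of each subject's
#' stationary PaO2 level; within-series fluctuation is an AR(1) process with
#' autocorrelation 0.8 and innovation scale fixed at 3 mmHg (see the methods
#' vignette for why these two variance components are separated).
#'
#' @param n_cases number of ILD (label 1) subjects.
#' @param n_controls number of non-ILD (label 0) subjects.
#' @param image_size side of the square grayscale image, pixels (>= 16).
#' @param series_length number of time steps T (>= 2).
#' @param series_channels number of physiological channels D (channel 1 is
#'   the PaO2-like channel, the rest are nuisance).
#' @param vocab_size token vocabulary size (>= 20).
#' @param signal_strength named numeric vector with entries `image`,
#'   `series`, `text`, each in `[0, 1]`; 0 removes the class signal from that
#'   modality, 1 is the full planted effect.
#' @param pao2_case_mean,pao2_control_mean stationary PaO2 means, mmHg.
#' @param pao2_sd between-subject PaO2 scatter, mmHg (> 0).
#' @param split_fraction fraction of subjects assigned to the training split
#'   (stratified by label).
#' @param rng_seed integer seed controlling sample content.
#' @param split_seed integer seed controlling the train/test split only.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_cases = 40L,
                             n_controls = 20L,
                             image_size = 64L,
                             series_length = 32L,
                             series_channels = 4L,
                             vocab_size = 60L,
                             signal_strength = c(image = 1, series = 1, text = 1),
                             pao2_case_mean = 85,
                             pao2_control_mean = 95,
                             pao2_sd = 5,
                             split_fraction = 0.8,
                             rng_seed = 1L,
                             split_seed = NULL) {
  ss <- c(image = 1, series = 1, text = 1)
  if (!is.null(names(signal_strength))) {
    ss[names(signal_strength)] <- signal_strength
  } else if (length(signal_strength) == 1L) {
    ss[] <- signal_strength
  } else {
    ss[] <- signal_strength
  }
  cfg <- structure(list(
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    image_size = as.integer(image_size),
    series_length = as.integer(series_length),
    series_channels = as.integer(series_channels),
    vocab_size = as.integer(vocab_size),
    signal_strength = ss,
    pao2_case_mean = pao2_case_mean,
    pao2_control_mean = pao2_control_mean,
    pao2_sd = pao2_sd,
    split_fraction = split_fraction,
    rng_seed = as.integer(rng_seed),
    split_seed = as.integer(split_seed %||% (rng_seed + 1L))
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is_count(cfg$n_cases) || !is_count(cfg$n_controls)) {
    stopf("generator_config: n_cases and n_controls must be >= 1")
  }
  if (!is_count(cfg$image_size, 16L)) stopf("generator_config: image_size must be >= 16")
  if (!is_count(cfg$series_length, 2L)) stopf("generator_config: series_length must be >= 2")
  if (!is_count(cfg$series_channels, 1L)) stopf("generator_config: series_channels must be >= 1")
  if (!is_count(cfg$vocab_size, 20L)) stopf("generator_config: vocab_size must be >= 20")
  if (any(cfg$signal_strength < 0) || any(cfg$signal_strength > 1)) {
    stopf("generator_config: signal strengths must lie in [0, 1]")
  }
  if (!is.finite(cfg$pao2_sd) || cfg$pao2_sd <= 0) stopf("generator_config: pao2_sd must be > 0")
  if (cfg$split_fraction < 0 || cfg$split_fraction > 1) {
    stopf("generator_config: split_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Model architecture configuration
#'
#' Describes the full multimodal architecture: the convolutional image
#' encoder, the bidirectional-LSTM series encoder, the self-attention text
#' encoder, and the attention-weighted fusion head. All encoders project to
#' a common feature width `d_model`.
#'
#' The `"table2"` profile instantiates the large published layout (224x224
#' RGB input, first convolution 3 -> 64 channels, series input width 10,
#' hidden size 20); it exists for parameter-count introspection and is not
#' intended for desk-scale training.
#'
#' @param d_model common modality feature width.
#' @param image list: `size`, `channels` (input), `blocks` (output channels
#'   per conv block), `kernel` (square kernel side).
#' @param series list: `channels` (input width D), `hidden` (per-direction
#'   LSTM hidden size), `pooling` (`"mean"` or `"last"`).
#' @param text list: `vocab`, `heads`, `score_scale` (`"sqrt_dk"` divides
#'   attention scores by sqrt(d_k); `"dk"` divides by d_k),
#'   `use_positional` (add sinusoidal positional encoding).
#' @param fusion list: `heads`, `projection_nonlinearity` (`"tanh"` or
#'   `"identity"`), `fuse_input` (`"mf"` fuses the attention-mixed tokens,
#'   `"alpha"` fuses the projected tokens directly).
#' @param n_classes number of output classes (2 = ILD vs non-ILD).
#' @param modalities character subset of `c("image", "series", "text")`
#'   naming the branches to instantiate (ablation mask).
#' @param profile `"reference"` (desk scale) or `"table2"`.
#' @return a list of class `model_config`.
#' @export
model_config <- function(d_model = 64L,
                         image = list(),
                         series = list(),
                         text = list(),
                         fusion = list(),
                         n_classes = 2L,
                         modalities = c("image", "series", "text"),
                         profile = c("reference", "table2")) {
  profile <- match.arg(profile)
  img_def <- list(size = 64L, channels = 1L, blocks = c(8L, 16L), kernel = 3L)
  ser_def <- list(channels = 4L, hidden = 20L, pooling = "mean")
  txt_def <- list(vocab = 60L, heads = 4L, score_scale = "sqrt_dk", use_positional = TRUE)
  fus_def <- list(heads = 4L, projection_nonlinearity = "tanh", fuse_input = "mf")
  if (profile == "table2") {
    img_def <- list(size = 224L, channels = 3L, blocks = c(64L, 64L), kernel = 3L)
    ser_def$channels <- 10L
  }
  cfg <- structure(list(
    d_model = as.integer(d_model),
    image = modifyList(img_def, image),
    series = modifyList(ser_def, series),
    text = modifyList(txt_def, text),
    fusion = modifyList(fus_def, fusion),
    n_classes = as.integer(n_classes),
    modalities = modalities,
    profile = profile
  ), class = "model_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  if (cfg$n_classes < 2L) stopf("model_config: n_classes must be >= 2")
  bad <- setdiff(cfg$modalities, c("image", "series", "text"))
  if (length(bad)) stopf("model_config: unknown modality '%s'", bad[1L])
  if (length(cfg$modalities) < 1L) stopf("model_config: modality mask must be non-empty")
  if (cfg$d_model %% cfg$text$heads != 0L) {
    stopf("model_config: text heads (%d) must divide d_model (%d)",
          cfg$text$heads, cfg$d_model)
  }
  if (cfg$d_model %% cfg$fusion$heads != 0L) {
    stopf("model_config: fusion heads (%d) must divide d_model (%d)",
          cfg$fusion$heads, cfg$d_model)
  }
  if (!cfg$series$pooling %in% c("mean", "last")) {
    stopf("model_config: series pooling must be 'mean' or 'last'")
  }
  if (!cfg$text$score_scale %in% c("sqrt_dk", "dk")) {
    stopf("model_config: score_scale must be 'sqrt_dk' or 'dk'")
  }
  invisible(cfg)
}

#' Training configuration (AdamW)
#'
#' Defaults: learning rate 1e-3, decoupled weight decay 1e-2 applied to
#' weight matrices (not biases), betas (0.9, 0.999), epsilon 1e-8, batch
#' size 16, 50 epochs.
#'
#' @param epochs number of passes over the training split.
#' @param batch_size mini-batch size.
#' @param learning_rate AdamW step size (> 0).
#' @param weight_decay decoupled weight decay coefficient.
#' @param beta1,beta2,epsilon AdamW moment parameters.
#' @param rng_seed seed controlling parameter init and shuffling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 50L,
                         batch_size = 16L,
                         learning_rate = 1e-3,
                         weight_decay = 1e-2,
                         beta1 = 0.9,
                         beta2 = 0.999,
                         epsilon = 1e-8,
                         rng_seed = 1L) {
  if (!is.finite(learning_rate) || learning_rate < 0) {
    stopf("train_config: learning_rate must be >= 0")
  }
  if (!is_count(batch_size)) stopf("train_config: batch_size must be >= 1")
  structure(list(
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    beta1 = beta1, beta2 = beta2, epsilon = epsilon,
    rng_seed = as.integer(rng_seed)
  ), class = "train_config")
}

#' Read a YAML experiment configuration
#'
#' Recognised top-level sections: `generator`, `model` (with sub-sections
#' `image_encoder`, `sequence_encoder`, `text_encoder`, `fusion`), `train`.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return list with elements `generator`, `model`, `train`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path) %||% list()
  g <- y$generator %||% list()
  gen <- do.call(generator_config, g)
  m <- y$model %||% list()
  mod <- model_config(
    d_model = m$d_model %||% 64L,
    image = m$image_encoder %||% list(),
    series = m$sequence_encoder %||% list(),
    text = m$text_encoder %||% list(),
    fusion = m$fusion %||% list(),
    modalities = m$modalities %||% c("image", "series", "text"),
    profile = m$profile %||% "reference"
  )
  tr <- do.call(train_config, y$train %||% list())
  list(generator = gen, model = mod, train = tr)
}

#' Hash a configuration for run provenance logs
#' @keywords internal
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
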