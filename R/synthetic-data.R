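# Synthetic multimodal cohort generator.
#
# Each subject carries three modalities plus a binary label (1 = ILD case,
# 0 = non-ILD control). The planted class signal per modality is:
#   image  - a periodic high-frequency "honeycomb" texture in a peripheral
#            ring of the lung field, amplitude proportional to strength;
#   series - a PaO2-like channel whose stationary level drops from the
#            control mean (95 mmHg) toward the case mean (85 mmHg);
#   text   - over-representation of a case-specific symptom sub-vocabulary.
# Strength 0 removes the signal entirely: both classes then share one
# distribution in that modality.

# Free constants of the generator (values documented in the methods vignette).
.gen_constants <- list(
  image = list(
    background = 0.35,   # mean grey level of the lung-field background
    lowfreq_amp = 0.08,  # amplitude of the smooth low-frequency field
    noise_sd = 0.04,     # i.i.d. pixel noise
    texture_amp = 0.06, # mean honeycomb amplitude at strength 1
    severity_sd = 0.7,   # between-subject scatter of the severity scale
    texture_period = 8,  # pixels per honeycomb cell
    ring = c(0.55, 0.95) # peripheral band, fraction of half-size
  ),
  series = list(
    phi = 0.8,           # AR(1) autocorrelation of within-series noise
    within_sd = 3,       # stationary sd of within-series fluctuation, mmHg
    nuisance_sd = 1      # sd of the label-free nuisance channels
  ),
  text = list(
    sub_vocab = 5L,      # tokens per class-specific symptom sub-vocabulary
    base_rate = 0.06,    # symptom-token probability in the opposite class
    gap = 0.10,          # additional own-class probability at strength 1
    len_range = c(15L, 35L)
  )
)

#' Peripheral texture mask used by the image generator
#'
#' Logical matrix marking the ring (radial distance between 55% and 95% of
#' the half-size) where the case-only honeycomb texture is planted.
#'
#' @param size image side in pixels.
#' @return logical `size x size` matrix.
#' @export
texture_mask <- function(size) {
  half <- (size + 1) / 2
  r <- sqrt(outer((seq_len(size) - half)^2, (seq_len(size) - half)^2, "+")) / (size / 2)
  ring <- .gen_constants$image$ring
  r >= ring[1L] & r <= ring[2L]
}

#' Generate one synthetic chest-image stand-in
#'
#' Background is a smooth low-frequency field plus Gaussian pixel noise.
#' For an ILD case (`label = 1`) a periodic honeycomb-like texture with mean
#' amplitude `0.06 * strength` is added inside the peripheral ring returned
#' by [texture_mask()]. Values are clipped to `[0, 1]`.
#'
#' @param label 0 (control) or 1 (case).
#' @param strength class-signal strength in `[0, 1]`.
#' @param size image side in pixels (>= 16).
#' @param seed integer seed; identical arguments give bit-identical images.
#' @return numeric `size x size` matrix in `[0, 1]`.
#' @export
generate_image <- function(label, strength = 1, size = 64L, seed = 1L) {
  if (!is_count(size, 16L)) stopf("generate_image: size must be >= 16")
  if (strength < 0 || strength > 1) stopf("generate_image: strength must lie in [0, 1]")
  if (!label %in% c(0, 1)) stopf("generate_image: label must be 0 or 1")
  k <- .gen_constants$image
  withr::with_seed(seed, {
    xs <- seq_len(size) / size
    u <- runif(2, 0.5, 1.5); ph <- runif(2, 0, 2 * pi)
    field <- k$lowfreq_amp * outer(cos(2 * pi * u[1L] * xs + ph[1L]),
                                   cos(2 * pi * u[2L] * xs + ph[2L]))
    img <- k$background + field +
      matrix(rnorm(size * size, 0, k$noise_sd), size, size)
    if (label == 1 && strength > 0) {
      # subject-level fibrosis severity: mean 1, so the expected in-mask
      # amplitude stays texture_amp * strength, but mild cases overlap the
      # control distribution as they do in real cohorts
      severity <- pmax(0, rnorm(1, 1, k$severity_sd))
      g <- seq_len(size)
      hc <- outer(sin(2 * pi * g / k$texture_period),
                  sin(2 * pi * g / k$texture_period))
      tex <- k$texture_amp * strength * severity * (1 + hc)
      m <- texture_mask(size)
      img[m] <- img[m] + tex[m]
    }
    pmin(pmax(img, 0), 1)
  })
}

# Stationary AR(1) series: mean 0, stationary sd `sd`, autocorrelation `phi`.
ar1_series <- function(n, phi, sd) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

#' Generate one synthetic physiological time series
#'
#' Channel 1 plays the role of PaO2: the subject's stationary level is drawn
#' from a normal with sd `cfg$pao2_sd` around a class mean, and the series
#' fluctuates around that level as an AR(1) process (autocorrelation 0.8,
#' within-series sd 3 mmHg). The case mean interpolates from the control
#' mean at strength 0 to `cfg$pao2_case_mean` at strength 1. Remaining
#' channels are label-free nuisance AR(1) noise.
#'
#' @param label 0 or 1.
#' @param strength class-signal strength in `[0, 1]`.
#' @param T_len number of time steps (>= 2).
#' @param D number of channels (>= 1).
#' @param cfg a [generator_config()] (supplies the PaO2 parameters).
#' @param seed integer seed.
#' @return numeric `T_len x D` matrix; column names name the channels.
#' @export
generate_series <- function(label, strength = 1, T_len = 32L, D = 4L,
                            cfg = generator_config(), seed = 1L) {
  if (!is_count(T_len, 2L)) stopf("generate_series: T must be >= 2")
  if (!is_count(D, 1L)) stopf("generate_series: D must be >= 1")
  if (!is.finite(cfg$pao2_sd) || cfg$pao2_sd <= 0) {
    stopf("generate_series: pao2_sd must be > 0")
  }
  if (strength < 0 || strength > 1) stopf("generate_series: strength must lie in [0, 1]")
  k <- .gen_constants$series
  mu <- if (label == 1) {
    cfg$pao2_control_mean - strength * (cfg$pao2_control_mean - cfg$pao2_case_mean)
  } else {
    cfg$pao2_control_mean
  }
  withr::with_seed(seed, {
    X <- matrix(0, T_len, D)
    level <- rnorm(1, mu, cfg$pao2_sd)
    X[, 1L] <- level + ar1_series(T_len, k$phi, k$within_sd)
    if (D > 1L) {
      for (d in 2:D) X[, d] <- ar1_series(T_len, k$phi, k$nuisance_sd)
    }
    colnames(X) <- c("pao2", if (D > 1L) paste0("ch", 2:D))
    X
  })
}

# Word forms for portable fixtures; ids beyond the two sub-vocabularies get
# generic forms.
token_word <- function(id) {
  case_words <- c("dyspnea", "honeycombing", "fibrosis", "crackles", "hypoxemia")
  ctrl_words <- c("clear", "stable", "normal", "unremarkable", "routine")
  k <- .gen_constants$text$sub_vocab
  out <- paste0("w", id)
  out[id < 2L * k] <- ctrl_words[pmax(id[id < 2L * k] - k + 1L, 1L)]
  out[id < k] <- case_words[id[id < k] + 1L]
  out
}

#' Generate one synthetic clinical-text token sequence
#'
#' Tokens are drawn from a background vocabulary mixed with two
#' class-specific symptom sub-vocabularies (ids `0..4` case-associated,
#' `5..9` control-associated). The own-class sub-vocabulary is sampled with
#' probability `0.06 + 0.10 * strength` per token, the opposite one with
#' probability 0.06, so the case/control symptom-token rate difference is
#' `0.10 * strength`. Document length is uniform on 15..35 tokens.
#'
#' @param label 0 or 1.
#' @param strength class-signal strength in `[0, 1]`.
#' @param vocab_size vocabulary size (>= 20: both sub-vocabularies plus at
#'   least as many background tokens).
#' @param seed integer seed.
#' @return integer vector of 0-based token ids (< `vocab_size`).
#' @export
generate_text <- function(label, strength = 1, vocab_size = 60L, seed = 1L) {
  if (!is_count(vocab_size, 20L)) {
    stopf("generate_text: vocab_size %d too small to hold both sub-vocabularies (need >= 20)",
          vocab_size)
  }
  if (strength < 0 || strength > 1) stopf("generate_text: strength must lie in [0, 1]")
  k <- .gen_constants$text
  own <- k$base_rate + k$gap * strength
  p_case <- if (label == 1) own else k$base_rate
  p_ctrl <- if (label == 1) k$base_rate else own
  withr::with_seed(seed, {
    n <- sample(seq.int(k$len_range[1L], k$len_range[2L]), 1L)
    cat3 <- sample(3L, n, replace = TRUE, prob = c(p_case, p_ctrl, 1 - p_case - p_ctrl))
    toks <- integer(n)
    toks[cat3 == 1L] <- sample.int(k$sub_vocab, sum(cat3 == 1L), replace = TRUE) - 1L
    toks[cat3 == 2L] <- k$sub_vocab +
      sample.int(k$sub_vocab, sum(cat3 == 2L), replace = TRUE) - 1L
    nb <- sum(cat3 == 3L)
    toks[cat3 == 3L] <- 2L * k$sub_vocab +
      sample.int(vocab_size - 2L * k$sub_vocab, nb, replace = TRUE) - 1L
    toks
  })
}

#' Generate a full multimodal cohort
#'
#' Produces `n_cases + n_controls` samples (defaults 40/20, the 2:1 cohort
#' shape), each with all three modalities, plus a manifest with a stratified
#' train/test split. Identical config and seed give bit-identical output.
#'
#' @param cfg a [generator_config()].
#' @return list with `samples` (list of multimodal samples: `sample_id`,
#'   `image`, `series`, `tokens`, `label`) and `manifest` (data frame with
#'   columns sample_id, image, series, text, label, split).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  validate_generator_config(cfg)
  n <- cfg$n_cases + cfg$n_controls
  labels <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
  ss <- cfg$signal_strength
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%04d", i)
    samples[[i]] <- list(
      sample_id = sid,
      image = generate_image(labels[i], ss[["image"]], cfg$image_size,
                             seed = derive_seed(cfg$rng_seed, i, 1L)),
      series = generate_series(labels[i], ss[["series"]], cfg$series_length,
                               cfg$series_channels, cfg,
                               seed = derive_seed(cfg$rng_seed, i, 2L)),
      tokens = generate_text(labels[i], ss[["text"]], cfg$vocab_size,
                             seed = derive_seed(cfg$rng_seed, i, 3L)),
      label = labels[i]
    )
  }
  split <- rep("test", n)
  withr::with_seed(cfg$split_seed, {
    for (lab in c(0L, 1L)) {
      idx <- which(labels == lab)
      n_tr <- round(cfg$split_fraction * length(idx))
      split[idx[sample.int(length(idx), n_tr)]] <- "train"
    }
  })
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, "", "sample_id"),
    image = sprintf("images/%s.png", vapply(samples, `[[`, "", "sample_id")),
    series = sprintf("series/%s.csv", vapply(samples, `[[`, "", "sample_id")),
    text = vapply(samples, `[[`, "", "sample_id"),
    label = labels,
    split = split,
    stringsAsFactors = FALSE
  )
  list(samples = samples, manifest = manifest)
}

#' Write a cohort to portable plain-text/PNG fixtures
#'
#' Layout under `directory`: `images/<id>.png` (8-bit grayscale),
#' `series/<id>.csv` (header = channel names, one row per time step),
#' `text.jsonl` (`{"id", "tokens", "raw_text"}` per line), `manifest.csv`.
#'
#' @param samples,manifest as returned by [generate_dataset()].
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_fixtures <- function(samples, manifest, directory) {
  dir.create(file.path(directory, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "series"), recursive = TRUE, showWarnings = FALSE)
  txt_lines <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image, file.path(directory, "images", paste0(s$sample_id, ".png")))
    write.csv(as.data.frame(s$series),
              file.path(directory, "series", paste0(s$sample_id, ".csv")),
              row.names = FALSE)
    txt_lines[i] <- jsonlite::toJSON(
      list(id = s$sample_id, tokens = as.integer(s$tokens),
           raw_text = paste(token_word(s$tokens), collapse = " ")),
      auto_unbox = TRUE)
  }
  writeLines(txt_lines, file.path(directory, "text.jsonl"))
  mpath <- file.path(directory, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort back from fixtures
#'
#' Inverse of [write_fixtures()]. Labels and tokens round-trip exactly;
#' series round-trip to the CSV's printed precision and images to 8-bit
#' quantization.
#'
#' @param directory fixture directory containing `manifest.csv`.
#' @return list with `samples` and `manifest` as in [generate_dataset()].
#' @export
read_fixtures <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stopf("read_fixtures: missing file: %s", mpath)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character", text = "character"))
  txt_path <- file.path(directory, "text.jsonl")
  tokens_by_id <- list()
  if (file.exists(txt_path) && length(readLines(txt_path)) > 0) {
    for (line in readLines(txt_path)) {
      rec <- jsonlite::fromJSON(line)
      tokens_by_id[[rec$id]] <- as.integer(rec$tokens)
    }
  }
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    ipath <- file.path(directory, row$image)
    spath <- file.path(directory, row$series)
    if (!file.exists(ipath)) stopf("read_fixtures: missing file: %s", ipath)
    if (!file.exists(spath)) stopf("read_fixtures: missing file: %s", spath)
    img <- png::readPNG(ipath)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    ser <- as.matrix(read.csv(spath, check.names = FALSE))
    toks <- tokens_by_id[[row$text]]
    if (is.null(toks)) stopf("read_fixtures: missing text record: %s", row$text)
    samples[[i]] <- list(sample_id = row$sample_id, image = img, series = ser,
                         tokens = toks, label = as.integer(row$label))
  }
  list(samples = samples, manifest = manifest)
}
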