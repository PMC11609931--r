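# Training loop, evaluation metrics, ablation bookkeeping, introspection, CLI.

make_small_dataset <- function(seed = 1L, n1 = 12L, n0 = 8L, strengths = 1) {
  generate_dataset(tiny_generator_config(n_cases = n1, n_controls = n0,
                                         rng_seed = seed,
                                         signal_strength = strengths))
}

test_that("zero learning rate leaves parameters and loss untouched", {
  ds <- make_small_dataset()
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 3L, learning_rate = 0, rng_seed = 2L)
  m <- train_model(ds, cfg, tc)
  expect_equal(m$loss_history, rep(m$loss_history[1L], 3L), tolerance = 1e-12)
  init <- init_parameters(cfg, 2L)
  expect_identical(flatten_params(m$params)$theta, flatten_params(init)$theta)
})

test_that("training is deterministic and reduces the loss on a strong signal", {
  ds <- make_small_dataset(seed = 11L, n1 = 20L, n0 = 12L)
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 8L, rng_seed = 3L)
  m1 <- train_model(ds, cfg, tc)
  m2 <- train_model(ds, cfg, tc)
  expect_equal(m1$loss_history, m2$loss_history, tolerance = 1e-10)
  expect_lt(tail(m1$loss_history, 1L), m1$loss_history[1L])
  # prediction on a training sample equals the forward pass used in training
  tr_idx <- which(ds$manifest$split == "train")[1L]
  s <- ds$samples[[tr_idx]]
  direct <- ildfusion:::model_forward_batch(
    list(s), m1$params, m1$config, m1$norm)$probs[, 1L]
  expect_lt(max(abs(predict(m1, list(s))$probs[, 1L] - direct)), 1e-10)
})

test_that("single-class training or evaluation sets are rejected", {
  ds <- make_small_dataset()
  keep <- vapply(ds$samples, `[[`, integer(1), "label") == 1L
  ds_one <- list(samples = ds$samples[keep],
                 manifest = ds$manifest[keep, ])
  expect_error(train_model(ds_one, tiny_model_config(), train_config(epochs = 1L)),
               "single class")
  expect_error(auc_mann_whitney(c(0.2, 0.8), c(1, 1)), "single class")
})

test_that("metric_report reproduces the hand-computed confusion example", {
  # confusion [[TN=8, FP=2], [FN=1, TP=9]]
  truth <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 8), 1, 1, 0, rep(1, 9))
  scores <- pred * 0.8 + 0.1
  rep_ <- metric_report(scores, pred, truth)
  expect_equal(rep_$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(rep_$recall, 0.9, tolerance = 1e-12)
  expect_equal(rep_$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9), tolerance = 1e-12)
  expect_equal(unname(rep_$confusion), matrix(c(8, 2, 1, 9), 2, byrow = TRUE))
  expect_equal(sum(rep_$confusion), 20)
  # f1 is the harmonic mean of precision and recall
  expect_equal(rep_$f1, 2 / (1 / rep_$precision + 1 / rep_$recall), tolerance = 1e-12)
  # perfectly separated scores
  perfect <- metric_report(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  # single-class truth: AUC NA with warning, other metrics intact
  expect_warning(one <- metric_report(c(0.2, 0.9), c(0, 1), c(1, 1)), "single")
  expect_true(is.na(one$auc))
  expect_equal(one$recall, 0.5)
})

test_that("rank-based AUC equals the all-pairs counting oracle", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      n <- sample(6:20, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
      expect_lt(abs(auc_mann_whitney(scores, labels) - auc_oracle(scores, labels)),
                1e-12)
    }
  })
})

test_that("roc points are monotone from (0,0) to (1,1)", {
  withr::with_seed(6, {
    scores <- runif(30)
    labels <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
  })
  roc <- roc_points(scores, labels)
  expect_equal(roc$fpr[1L], 0)
  expect_equal(roc$tpr[1L], 0)
  expect_equal(tail(roc$fpr, 1L), 1)
  expect_equal(tail(roc$tpr, 1L), 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("ablation reuses seeds, matches a plain run, and covers six subsets", {
  ds <- make_small_dataset(seed = 21L, n1 = 14L, n0 = 8L)
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 2L, rng_seed = 7L)
  res <- ablate(ds, cfg, tc)
  expect_length(res$reports, 6L)
  expect_setequal(names(res$reports), names(ablation_subsets()))
  # the all-three subset equals a plain train + evaluate with the same seed
  cfg_all <- cfg
  cfg_all$modalities <- c("text", "image", "series")
  plain <- evaluate_model(train_model(ds, cfg_all, tc), ds)
  expect_equal(res$reports$text_image_series$auc, plain$auc, tolerance = 1e-12)
  expect_equal(unname(res$reports$text_image_series$confusion),
               unname(plain$confusion))
  expect_error(ablate(ds, cfg, tc, subsets = list(none = character(0))), "empty")
})

test_that("parameter counting matches the enumerated theta exactly", {
  expect_identical(param_count_linear(256L, 10L), 2570L)
  expect_identical(param_count_conv2d(3L, 64L, 3L), 1792L)
  withr::with_seed(8, {
    for (rep in 1:10) {
      cfg <- model_config(
        d_model = sample(c(4L, 8L), 1),
        image = list(size = 16L, channels = sample(1:2, 1),
                     blocks = sample(2:4, sample(1:2, 1)), kernel = 3L),
        series = list(channels = sample(1:3, 1), hidden = sample(2:5, 1)),
        text = list(vocab = sample(20:30, 1), heads = 2L),
        fusion = list(heads = 2L),
        modalities = sample(c("image", "series", "text"),
                            sample(1:3, 1)))
      total <- count_parameters(cfg)$total
      theta <- flatten_params(init_parameters(cfg, rep))$theta
      expect_identical(as.integer(total), length(theta))
    }
  })
})

test_that("FLOP estimates follow the analytic MAC formulas", {
  # 1x1 conv on one channel costs exactly H*W MACs
  expect_equal(conv_macs(13L, 9L, 1L, 1L), 117)
  # doubling the side at 1x1 kernel multiplies MACs exactly by 4
  expect_equal(conv_macs(32L, 32L, 1L, 1L), 4 * conv_macs(16L, 16L, 1L, 1L))
  # general formula
  expect_equal(conv_macs(10L, 10L, 3L, 3L, 2L, 4L), 8 * 8 * 9 * 8)
  fl <- estimate_flops(tiny_model_config())
  expect_equal(fl$total_flops, 2 * fl$total_macs)
  # matrix-vector product d x d costs d^2 MACs: the fusion projections row
  # counts k * d^2
  row <- fl$table$macs[fl$table$layer == "Fusion projections"]
  expect_equal(row, 3 * 8^2)
  # zero-layer config: nothing but the always-present fusion head
  cfg1 <- tiny_model_config(modalities = "series")
  expect_lt(estimate_flops(cfg1)$total_macs, fl$total_macs)
})

test_that("cli commands produce their artifacts and fail loudly", {
  out1 <- file.path(withr::local_tempdir(), "d1")
  out2 <- file.path(withr::local_tempdir(), "d2")
  cfg_yaml <- file.path(withr::local_tempdir(), "cfg.yaml")
  yaml::write_yaml(list(
    generator = list(n_cases = 10L, n_controls = 6L, image_size = 16L,
                     series_length = 5L, series_channels = 2L, vocab_size = 25L),
    model = list(d_model = 8L,
                 image_encoder = list(size = 16L, channels = 1L,
                                      blocks = c(2L, 3L), kernel = 3L),
                 sequence_encoder = list(channels = 2L, hidden = 3L),
                 text_encoder = list(vocab = 25L, heads = 2L),
                 fusion = list(heads = 2L)),
    train = list(epochs = 2L, rng_seed = 1L)), cfg_yaml)
  # simulate twice with one seed: identical directory contents
  expect_identical(run_cli(c("simulate", "--config", cfg_yaml, "--seed", "5",
                             "--out", out1)), 0L)
  expect_identical(run_cli(c("simulate", "--config", cfg_yaml, "--seed", "5",
                             "--out", out2)), 0L)
  for (f in c("manifest.csv", "text.jsonl")) {
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
  }
  img1 <- list.files(file.path(out1, "images"), full.names = TRUE)
  img2 <- list.files(file.path(out2, "images"), full.names = TRUE)
  expect_identical(lapply(img1, readBin, what = "raw", n = 1e6),
                   lapply(img2, readBin, what = "raw", n = 1e6))
  # evaluate without a checkpoint: nonzero exit naming the file
  msgs <- capture.output(
    st <- run_cli(c("evaluate", "--data", out1, "--checkpoint",
                    file.path(out1, "nope.rds"), "--out", out1)),
    type = "message")
  expect_identical(st, 1L)
  expect_true(any(grepl("nope.rds", msgs)))
  # unknown command and unknown flag are usage errors
  expect_identical(run_cli("frobnicate"), 2L)
  expect_identical(run_cli(c("train", "--bogus", "1")), 1L)
  # train then evaluate end to end
  run_dir <- file.path(withr::local_tempdir(), "run")
  expect_identical(run_cli(c("train", "--config", cfg_yaml, "--data", out1,
                             "--seed", "2", "--out", run_dir)), 0L)
  expect_true(file.exists(file.path(run_dir, "checkpoint.rds")))
  expect_true(file.exists(file.path(run_dir, "loss.csv")))
  ev_dir <- file.path(withr::local_tempdir(), "ev")
  expect_identical(run_cli(c("evaluate", "--data", out1, "--checkpoint",
                             file.path(run_dir, "checkpoint.rds"),
                             "--out", ev_dir)), 0L)
  metrics <- jsonlite::fromJSON(file.path(ev_dir, "metrics.json"))
  expect_true(all(c("precision", "recall", "f1", "auc", "confusion") %in%
                  names(metrics)))
  roc <- read.csv(file.path(ev_dir, "roc.csv"))
  expect_identical(names(roc), c("fpr", "tpr"))
  # ablate writes exactly six report files
  ab_dir <- file.path(withr::local_tempdir(), "ab")
  expect_identical(run_cli(c("ablate", "--config", cfg_yaml, "--data", out1,
                             "--seed", "3", "--out", ab_dir)), 0L)
  expect_length(list.files(ab_dir, pattern = "^metrics_.*\\.json$"), 6L)
  expect_true(file.exists(file.path(ab_dir, "summary.tsv")))
  # inspect prints the parameter table
  ins <- capture.output(run_cli(c("inspect", "--config", cfg_yaml)),
                        type = "message")
  expect_true(any(grepl("Total params", ins)))
})
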