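# Modality projection, cross-modality attention, fusion weights, classifier.

test_that("project_modalities applies the configured nonlinearity", {
  d <- 4L
  withr::with_seed(1, {
    H_i <- rnorm(d); H_n <- rnorm(d); H_t <- rnorm(d)
    W <- matrix(rnorm(d * d), d)
  })
  # identity weights + identity nonlinearity: alpha = H exactly
  id <- list(W_i = diag(d), W_n = diag(d), W_t = diag(d), nonlinearity = "identity")
  a <- project_modalities(H_i, H_n, H_t, id)
  expect_identical(a$alpha_i, H_i)
  expect_identical(a$alpha_n, H_n)
  expect_identical(a$alpha_t, H_t)
  # zero features map to tanh(0) = 0
  proj <- list(W_i = W, W_n = W, W_t = W)
  z <- project_modalities(numeric(d), numeric(d), numeric(d), proj)
  expect_equal(z$alpha_i, numeric(d))
  # random instance against a direct matrix-vector oracle
  got <- project_modalities(H_i, H_n, H_t, proj)
  expect_lt(max(abs(got$alpha_i - tanh(as.numeric(W %*% H_i)))), 1e-10)
  expect_lt(max(abs(got$alpha_t - tanh(as.numeric(W %*% H_t)))), 1e-10)
  expect_error(project_modalities(numeric(3), H_n, H_t, proj), "length")
})

test_that("fuse_attention is symmetric and equivariant over modality tokens", {
  d <- 4L
  withr::with_seed(2, {
    a1 <- rnorm(d); a2 <- rnorm(d); a3 <- rnorm(d)
    p <- list(Wq = matrix(rnorm(d * d), d), Wk = matrix(rnorm(d * d), d),
              Wv = matrix(rnorm(d * d), d), Wo = matrix(rnorm(d * d), d),
              heads = 1L)
  })
  # identical tokens give identical output rows
  same <- fuse_attention(a1, a1, a1, p)
  expect_lt(max(abs(same[1L, ] - same[2L, ])), 1e-12)
  expect_lt(max(abs(same[1L, ] - same[3L, ])), 1e-12)
  # swapping two inputs swaps the corresponding rows (shared projections)
  b12 <- fuse_attention(a1, a2, a3, p)
  b21 <- fuse_attention(a2, a1, a3, p)
  expect_lt(max(abs(b12[1L, ] - b21[2L, ])), 1e-10)
  expect_lt(max(abs(b12[2L, ] - b21[1L, ])), 1e-10)
  expect_lt(max(abs(b12[3L, ] - b21[3L, ])), 1e-10)
  # H = 1, identity projections, equal scores: each row is the token mean
  pu <- list(Wq = matrix(0, d, d), Wk = matrix(0, d, d), Wv = diag(d),
             Wo = diag(d), heads = 1L)
  bu <- fuse_attention(a1, a2, a3, pu)
  target <- (a1 + a2 + a3) / 3
  for (r in 1:3) expect_equal(bu[r, ], target, tolerance = 1e-12)
})

test_that("fusion weights live on the simplex with closed-form values", {
  expect_equal(fusion_weights(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(fusion_weights(log(c(1, 2, 1))), c(0.25, 0.5, 0.25))
  expect_lt(max(abs(fusion_weights(c(0.3, -1, 2)) -
                    fusion_weights(c(0.3, -1, 2) + 11))), 1e-12)
  expect_error(fusion_weights(c(1, NaN, 0)), "finite")
})

test_that("weighted_fuse combines tokens per the simplex weights", {
  withr::with_seed(3, beta <- matrix(rnorm(12), 3, 4))
  expect_equal(weighted_fuse(beta, c(0, 1, 0)), beta[2L, ])
  same <- rbind(beta[1L, ], beta[1L, ], beta[1L, ])
  expect_equal(weighted_fuse(same, c(0.2, 0.5, 0.3)), beta[1L, ])
  for (s in 1:20) {
    withr::with_seed(s, {
      k <- sample(2:4, 1); d <- sample(2:5, 1)
      B <- matrix(rnorm(k * d), k)
      w <- fusion_weights(rnorm(k))
    })
    want <- numeric(d)
    for (m in seq_len(k)) want <- want + w[m] * B[m, ]
    expect_lt(max(abs(weighted_fuse(B, w) - want)), 1e-10)
  }
  expect_error(weighted_fuse(beta, c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("classifier and cross-entropy match closed forms", {
  expect_equal(classify(numeric(3), list(W = matrix(0, 2, 3), b = c(0, 0))),
               c(0.5, 0.5))
  expect_equal(classify(c(1), list(W = matrix(c(0, log(3)), 2, 1), b = c(0, 0))),
               c(0.25, 0.75))
  withr::with_seed(4, {
    for (rep in 1:100) {
      M <- rnorm(5)
      cls <- list(W = matrix(rnorm(15), 3, 5), b = rnorm(3))
      expect_equal(sum(classify(M, cls)), 1, tolerance = 1e-12)
    }
  })
  expect_equal(cross_entropy(c(1, 0), c(1, 0)), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(c(0.5, 0.5), c(0, 1)), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.25, 0.75), c(0, 1)), log(4 / 3), tolerance = 1e-12)
  expect_error(cross_entropy(c(0.5, 0.5), c(0.4, 0.6)), "one-hot")
  expect_error(classify(numeric(4), list(W = matrix(0, 2, 3), b = c(0, 0))), "width")
})

test_that("predict_sample is deterministic, breaks ties low, needs all masked modalities", {
  cfg <- tiny_model_config()
  gen <- tiny_generator_config()
  ds <- generate_dataset(gen)
  p <- init_parameters(cfg, 9L)
  s <- ds$samples[[1L]]
  r1 <- predict_sample(s, p, cfg)
  r2 <- predict_sample(s, p, cfg)
  expect_identical(r1, r2)
  expect_equal(sum(r1$probs), 1, tolerance = 1e-9)
  expect_true(all(r1$fusion_weights >= 0))
  expect_equal(sum(r1$fusion_weights), 1, tolerance = 1e-9)
  # symmetric initialisation producing equal logits: tie broken to class 0
  p_tie <- p
  p_tie[["fusion.cls.W"]][] <- 0
  p_tie[["fusion.cls.b"]][] <- 0
  expect_identical(predict_sample(s, p_tie, cfg)$label, 0L)
  # a sample missing a masked-in modality errors
  s_no_img <- s
  s_no_img$image <- NULL
  expect_error(predict_sample(s_no_img, p, cfg), "missing")
})

test_that("forward pass yields simplex outputs across a synthetic batch", {
  cfg <- tiny_model_config()
  ds <- generate_dataset(tiny_generator_config(n_cases = 30L, n_controls = 20L))
  p <- init_parameters(cfg, 10L)
  for (s in ds$samples) {
    r <- predict_sample(s, p, cfg)
    expect_equal(sum(r$probs), 1, tolerance = 1e-9)
    expect_true(all(r$fusion_weights >= 0) &&
                abs(sum(r$fusion_weights) - 1) < 1e-9)
  }
})

test_that("masking a modality keeps the fused vector in the remaining hull", {
  # with identity-style fusion (fuse_input = "alpha") the fused vector is a
  # convex combination of the remaining projected tokens
  cfg <- tiny_model_config(fusion = list(heads = 2L, fuse_input = "alpha"),
                           modalities = c("image", "series"))
  ds <- generate_dataset(tiny_generator_config())
  p <- init_parameters(cfg, 11L)
  s <- ds$samples[[1L]]
  fwd <- ildfusion:::model_forward_batch(list(s), p, cfg)
  fus <- fwd$fus[[1L]]
  expect_identical(nrow(fus$beta), 2L)
  for (k in seq_len(ncol(fus$beta))) {
    expect_true(fus$M[k] >= min(fus$beta[, k]) - 1e-12 &&
                fus$M[k] <= max(fus$beta[, k]) + 1e-12)
  }
})

test_that("full-model gradients pass central finite differences", {
  cfg <- tiny_model_config()
  ds <- generate_dataset(tiny_generator_config(split_fraction = 1))
  batch <- ds$samples[1:3]
  labels <- vapply(batch, `[[`, integer(1), "label")
  norm <- ildfusion:::series_norm_stats(batch)
  p <- init_parameters(cfg, 42L)
  fp <- flatten_params(p)
  loss_fn <- function(theta) {
    pp <- unflatten_params(theta, fp$skeleton)
    fwd <- ildfusion:::model_forward_batch(batch, pp, cfg, norm)
    ildfusion:::model_backward_batch(fwd, labels, pp, cfg)$loss
  }
  fwd <- ildfusion:::model_forward_batch(batch, p, cfg, norm)
  ga <- flatten_params(
    ildfusion:::model_backward_batch(fwd, labels, p, cfg)$grads)$theta
  # sample parameters from every group, plus ensure coverage of each array
  withr::with_seed(12, idx <- sort(sample(length(fp$theta), 150L)))
  starts <- cumsum(c(1, head(vapply(fp$skeleton, prod, numeric(1)), -1)))
  idx <- sort(unique(c(idx, as.integer(starts))))
  gn <- numeric_gradient(loss_fn, fp$theta, idx = idx)
  expect_lt(max(rel_err(gn, ga[idx])), 1e-3)
})
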