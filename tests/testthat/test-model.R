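# The classifier's backpropagation is hand-derived; the first test checks
# every architecture variant against central-difference gradients, which
# guards the whole training path.

numeric_grad_check <- function(rnn_type, conv, p = 7, q = 6, h = 6, B = 3) {
  cfg <- model_config(gru_units = h, conv_filters = conv, kernel_size = 3,
                      pool_size = 2, dropout_rates = c(0, 0),
                      dense_sizes = c(8, 5, 1), rnn_type = rnn_type, seed = 3)
  m <- build_model(cfg, c(p, q))
  cc <- lagnet:::cpp_config(cfg, c(p, q))
  set.seed(11)
  X <- array(rnorm(p * q * B), dim = c(p, q, B))
  y <- rep(c(1, 0), length.out = B)
  g <- lagnet:::nn_batch(m$theta + 0, cc, X, y, TRUE)$grad
  eps <- 1e-6
  idx <- sort(sample(length(m$theta), min(60, length(m$theta))))
  num <- vapply(idx, function(i) {
    tp <- m$theta + 0; tp[i] <- tp[i] + eps
    tm <- m$theta + 0; tm[i] <- tm[i] - eps
    (lagnet:::nn_batch(tp, cc, X, y, TRUE)$loss -
       lagnet:::nn_batch(tm, cc, X, y, TRUE)$loss) / (2 * eps)
  }, 1)
  max(abs(num - g[idx]) / pmax(1, abs(num)))
}

test_that("analytic gradients match numerical differentiation", {
  set.seed(30)
  expect_lt(numeric_grad_check("bigru", c(3, 2)), 1e-6)
  expect_lt(numeric_grad_check("gru", c(3, 2)), 1e-6)
  expect_lt(numeric_grad_check("lstm", c(3, 2)), 1e-6)
  expect_lt(numeric_grad_check("rnn", c(3, 2)), 1e-6)
  expect_lt(numeric_grad_check("none", c(3, 2)), 1e-6)   # CNN-only
  expect_lt(numeric_grad_check("bigru", integer(0)), 1e-6)  # BiGRU-only
})

test_that("model construction is seeded and validates shapes", {
  cfg <- tiny_model_cfg(seed = 4)
  m1 <- build_model(cfg, c(8, 8))
  m2 <- build_model(cfg, c(8, 8))
  expect_identical(m1$theta, m2$theta)
  expect_gt(length(m1$theta), 0)

  # forward pass of an all-zero matrix lands strictly inside (0, 1)
  s <- predict(m1, list(matrix(0, 8, 8)))
  expect_true(s > 0 && s < 1)

  # a kernel larger than the map names the offending layer
  expect_error(build_model(model_config(gru_units = 2, conv_filters = c(4, 4),
                                        dense_sizes = c(8, 4, 1)),
                           c(5, 5)),
               "conv layer")
  expect_error(model_config(dense_sizes = c(512, 128, 2)), "ending in 1")
  expect_error(model_config(conv_filters = c(8, 8, 8, 8, 8)), "at most 4")
})

test_that("prediction is order-preserving and batch-size independent", {
  m <- build_model(tiny_model_cfg(seed = 6), c(8, 8))
  set.seed(31)
  mats <- replicate(7, matrix(rnorm(64), 8, 8), simplify = FALSE)
  s_all <- predict(m, mats)
  s_rev <- predict(m, rev(mats))
  expect_equal(s_all, rev(s_rev), tolerance = 1e-12)
  s_one <- vapply(mats, function(x) predict(m, list(x)), 1)
  expect_equal(s_all, s_one, tolerance = 1e-6)

  expect_error(predict(m, list(matrix(0, 5, 8))), "does not match")
})

test_that("training memorizes a small separable set and early-stops", {
  set.seed(32)
  pos <- replicate(5, {
    z <- matrix(0, 8, 8); z[, 3] <- 3 + rnorm(8, sd = 0.2); z
  }, simplify = FALSE)
  neg <- replicate(5, matrix(abs(rnorm(64, sd = 0.3)), 8, 8),
                   simplify = FALSE)
  x <- c(pos, neg); y <- rep(c(1, 0), each = 5)
  cfg <- model_config(gru_units = 8, conv_filters = c(4), kernel_size = 3,
                      pool_size = 2, dense_sizes = c(16, 8, 1),
                      batch_size = 4, epochs = 60, patience = 60,
                      learning_rate = 0.05, seed = 2)
  m <- train_model(build_model(cfg, c(8, 8)), x, y, x, y)
  train_scores <- predict(m, x)
  expect_equal(compute_metrics(train_scores, y)$auroc, 1)
  expect_true(m$trained)
  expect_s3_class(m$history, "data.frame")

  expect_error(train_model(build_model(cfg, c(8, 8)), pos, rep(1, 5), x, y),
               "single class")
})

test_that("training is reproducible for a fixed seed", {
  sim <- simulate_dataset(tiny_synth_cfg())
  win <- default_window_config(160, p = 8, q = 8, m = 4, n = 4)
  pairs <- build_pair_samples(
    filter_gold_standard(sim$network, sim$expr), sim$expr, seed = 2)
  feats <- featurize_pairs(pairs, sim$expr, win)
  cfg <- tiny_model_cfg(seed = 9, epochs = 2)
  m1 <- train_model(build_model(cfg, c(8, 8)), feats, pairs$label,
                    feats, pairs$label)
  m2 <- train_model(build_model(cfg, c(8, 8)), feats, pairs$label,
                    feats, pairs$label)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$theta, m2$theta)
})

test_that("shuffled labels give chance-level validation performance", {
  sim <- simulate_dataset(tiny_synth_cfg())
  win <- default_window_config(160, p = 8, q = 8, m = 4, n = 4)
  pairs <- build_pair_samples(
    filter_gold_standard(sim$network, sim$expr), sim$expr, seed = 2)
  feats <- featurize_pairs(pairs, sim$expr, win)
  n <- nrow(pairs)
  aurocs <- vapply(1:5, function(s) {
    set.seed(s)
    y_shuf <- sample(pairs$label)           # break the feature-label link
    repeat {  # both halves need both classes
      tr <- sample(n, floor(n / 2))
      va <- setdiff(seq_len(n), tr)
      if (length(unique(y_shuf[tr])) == 2 &&
          length(unique(y_shuf[va])) == 2) break
    }
    cfg <- tiny_model_cfg(seed = s, epochs = 3)
    m <- train_model(build_model(cfg, c(8, 8)),
                     feats[tr], y_shuf[tr], feats[va], y_shuf[va])
    compute_metrics(predict(m, feats[va]), y_shuf[va])$auroc
  }, 1)
  expect_lt(abs(mean(aurocs) - 0.5), 0.2)
})
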