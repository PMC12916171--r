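test_that("the generator is a deterministic function of its configuration", {
  a <- simulate_dataset(tiny_synth_cfg())
  b <- simulate_dataset(tiny_synth_cfg())
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$lags, b$lags)
  c <- simulate_dataset(tiny_synth_cfg(seed = 4))
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("noiseless planted edges are exact lagged copies of their TF", {
  cfg <- synthetic_config(n_genes = 8, n_cells = 200, n_tfs = 2, n_edges = 3,
                          lag_range = c(6, 20), effect = 1, noise_sd = 0,
                          smoothness = 40, seed = 5)
  sim <- simulate_dataset(cfg)
  v <- sim$expr$values
  for (e in seq_len(nrow(sim$lags))) {
    tf <- sim$lags$tf[e]; tg <- sim$lags$target[e]; lag <- sim$lags$lag[e]
    overlap <- (lag + 1):200
    expect_equal(unname(v[tg, overlap]), unname(v[tf, overlap - lag]),
                 tolerance = 1e-12)
  }
  expect_true(all(v >= 0))
  expect_equal(unname(sim$expr$pseudotime), as.numeric(1:200))
})

test_that("delay-matrix column argmax recovers the planted lag", {
  # noiseless single-edge datasets across lags and window geometries
  combos <- expand.grid(n = c(2, 5), lag_mult = 1:5)
  for (i in seq_len(nrow(combos))) {
    n <- combos$n[i]
    tau <- n * combos$lag_mult[i]
    cfg <- synthetic_config(n_genes = 3, n_cells = 240, n_tfs = 1,
                            n_edges = 1, lag_range = c(tau, tau),
                            noise_sd = 0, smoothness = 40, seed = 30 + i)
    sim <- simulate_dataset(cfg)
    win <- default_window_config(240, p = 8, q = 8, m = n, n = n)
    M <- build_delay_matrix(sim$expr$values[sim$lags$tf[1], ],
                            sim$expr$values[sim$lags$target[1], ], win)
    expect_equal(which.max(colMeans(M$values)), 1 + tau / n)
  }
})

test_that("benchmark files round-trip through the loaders", {
  dir <- withr::local_tempdir()
  sim <- make_benchmark(tiny_synth_cfg(), dir)
  expect_true(all(file.exists(unlist(sim$paths))))

  expr2 <- load_expression(sim$paths$expression, sim$paths$pseudotime)
  expect_equal(expr2$values, sim$expr$values, tolerance = 1e-12)
  expect_equal(cell_ids(expr2), cell_ids(sim$expr))

  net2 <- load_network(sim$paths$gold)
  expect_setequal(paste(net2$tf, net2$target),
                  paste(sim$network$tf, sim$network$target))
  expect_equal(nrow(net2), 10)  # config echo

  manifest <- jsonlite::read_json(sim$paths$manifest, simplifyVector = TRUE)
  expect_equal(manifest$config$n_edges, 10)
  expect_equal(nrow(manifest$lags), 10)
})

test_that("decoy pairs carry weaker delay signal than planted pairs", {
  sim <- simulate_dataset(tiny_synth_cfg())
  win <- default_window_config(160, p = 8, q = 8, m = 4, n = 4)
  v <- sim$expr$values
  edge <- sim$lags[1, ]
  decoy <- setdiff(gene_ids(sim$expr),
                   c(sim$lags$target, unique(sim$lags$tf)))[1]
  m_true <- mean(abs(build_delay_matrix(v[edge$tf, ], v[edge$target, ],
                                        win)$values))
  m_decoy <- mean(abs(build_delay_matrix(v[edge$tf, ], v[decoy, ],
                                         win)$values))
  expect_gt(m_true, m_decoy)
})

test_that("realized noise variance tracks the configured noise_sd", {
  devs <- vapply(1:20, function(s) {
    cfg_n <- synthetic_config(n_genes = 12, n_cells = 150, n_tfs = 3,
                              n_edges = 5, lag_range = c(4, 10),
                              noise_sd = 0.5, smoothness = 30, seed = s)
    cfg_0 <- synthetic_config(n_genes = 12, n_cells = 150, n_tfs = 3,
                              n_edges = 5, lag_range = c(4, 10),
                              noise_sd = 0, smoothness = 30, seed = s)
    noisy <- simulate_dataset(cfg_n)$expr$values
    clean <- simulate_dataset(cfg_0)$expr$values
    mean(apply(noisy - clean, 1, var))   # the shift is constant per matrix
  }, 1)
  expect_lt(abs(mean(devs) - 0.25), 0.05)  # noise_sd^2 within 20%
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(n_genes = 10, n_tfs = 4, n_edges = 7),
               "infeasible edge count")
  expect_error(synthetic_config(n_cells = 100, lag_range = c(5, 30)),
               "T/4")
  expect_error(synthetic_config(noise_sd = -1), "nonnegative")
})
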