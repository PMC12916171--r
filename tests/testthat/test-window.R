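test_that("segment bounds follow the printed index arithmetic", {
  cfg <- window_config(p = 4, q = 4, m = 2, n = 2, w = 3)
  b <- segment_bounds(2, 2, cfg)
  expect_equal(b$tf, c(3, 5))
  expect_equal(b$target, c(5, 7))

  b0 <- segment_bounds(1, 1, cfg)
  expect_equal(b0$tf, c(1, 3))
  expect_equal(b0$target, c(1, 3))

  # the published large-dataset configuration ends exactly at cell 1071
  big <- window_config(p = 64, q = 64, m = 5, n = 5, w = 441)
  expect_equal(segment_bounds(64, 64, big)$target[2], 1071)

  expect_error(segment_bounds(5, 1, cfg), "1..p")
  expect_error(segment_bounds(1, 0, cfg), "1..q")
})

test_that("required cell count closes the segment formulas", {
  expect_equal(required_cells(window_config(64, 64, 5, 5, 441)), 1071)
  expect_equal(required_cells(window_config(1, 1, 3, 3, 17)), 17)

  set.seed(14)
  for (rep in 1:20) {
    cfg <- window_config(sample(1:6, 1), sample(1:6, 1),
                         sample(1:4, 1), sample(1:4, 1), sample(3:9, 1))
    ends <- max(vapply(seq_len(cfg$p), function(k) {
      max(vapply(seq_len(cfg$q), function(l) {
        segment_bounds(k, l, cfg)$target[2]
      }, 1))
    }, 1))
    expect_equal(required_cells(cfg), ends)
  }
})

test_that("automatic window solving uses the whole trajectory", {
  cfg <- default_window_config(1071)
  expect_equal(unlist(cfg[c("p", "q", "m", "n", "w")]),
               c(p = 64, q = 64, m = 5, n = 5, w = 441))

  # boundary feasibility: exactly enough cells for w = 3
  T_min <- (64 - 1) * 5 + (64 - 1) * 5 + 3
  expect_equal(default_window_config(T_min)$w, 3)

  # grid halving kicks in for short trajectories and stays feasible
  set.seed(15)
  for (T_len in sample(50:1500, 30)) {
    cfg <- default_window_config(T_len)
    expect_lte(required_cells(cfg), T_len)
    expect_gte(cfg$w, 3)
  }
  # even a 1x1 grid needs w >= 3 cells
  expect_equal(default_window_config(4)$p, 1)
  expect_error(default_window_config(2), "too short")
})

test_that("delay matrices match the brute-force double-loop oracle", {
  cfg <- window_config(p = 8, q = 8, m = 2, n = 2, w = 11)
  T_len <- required_cells(cfg) + 1
  set.seed(16)
  for (rep in 1:5) {
    x <- rnorm(T_len); y <- rnorm(T_len)
    M <- build_delay_matrix(x, y, cfg)
    expect_lt(max(abs(M$values - oracle_delay_matrix(x, y, cfg))), 1e-10)
    expect_true(all(M$values >= -1 & M$values <= 1))
  }
})

test_that("delay matrix honors degenerate and identity cases", {
  cfg <- window_config(p = 5, q = 5, m = 2, n = 2, w = 5)
  T_len <- required_cells(cfg)
  set.seed(17)
  x <- rnorm(T_len)
  same <- build_delay_matrix(x, x, cfg)
  expect_equal(unname(same$values[, 1]), rep(1, 5))  # zero lag, identical

  const <- build_delay_matrix(x, rep(2, T_len), cfg)
  expect_true(all(const$values == 0))

  expect_error(build_delay_matrix(x[1:10], x[1:10], cfg), "requires")
})

test_that("delay matrices are affine-invariant but not swap-symmetric", {
  cfg <- window_config(p = 6, q = 6, m = 2, n = 2, w = 7)
  T_len <- required_cells(cfg)
  set.seed(18)
  for (rep in 1:5) {
    x <- rnorm(T_len); y <- rnorm(T_len)
    M0 <- build_delay_matrix(x, y, cfg)$values
    M1 <- build_delay_matrix(3.7 * x + 2, 0.5 * y - 11, cfg)$values
    expect_equal(M0, M1, tolerance = 1e-10)
  }
  # a lagged pair: swapping the roles does not transpose the matrix
  sig <- sin(seq(0, 6 * pi, length.out = T_len + 6))
  tf <- sig[7:(T_len + 6)]
  tg <- sig[1:T_len]  # target = tf delayed by 6 cells
  A <- build_delay_matrix(tf, tg, cfg)$values
  B <- build_delay_matrix(tg, tf, cfg)$values
  expect_gt(max(abs(A - t(B))), 0.1)
})

test_that("heatmap export writes a file and rejects invalid matrices", {
  cfg <- window_config(p = 4, q = 4, m = 1, n = 1, w = 4)
  x <- rnorm(required_cells(cfg))
  M <- build_delay_matrix(x, x, cfg, tf_id = "a", target_id = "b")
  path <- withr::local_tempfile(fileext = ".png")
  plot_delay_heatmap(M, path)
  expect_true(file.exists(path) && file.size(path) > 0)

  M$values[1, 1] <- 1.5
  expect_error(plot_delay_heatmap(M, path), "outside")
})
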