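test_that("loading reorders cells by pseudotime with a stable sort", {
  dir <- withr::local_tempdir()
  m <- matrix(1:12, 3, 4,
              dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:4)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file.path(dir, "e.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = paste0("c", 1:4),
                                pt = c(0.4, 0.1, 0.3, 0.2)),
                     file.path(dir, "pt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  expr <- load_expression(file.path(dir, "e.tsv"),
                          file.path(dir, "pt.tsv"))
  expect_equal(cell_ids(expr), c("c2", "c4", "c3", "c1"))
  expect_equal(unname(expr$values["gA", ]), c(4, 10, 7, 1))
  expect_equal(unname(expr$pseudotime), c(0.1, 0.2, 0.3, 0.4))

  # ties keep input order (stable sort)
  e2 <- expression_matrix(m, pseudotime = c(1, 0, 1, 0))
  expect_equal(cell_ids(e2), c("c2", "c4", "c1", "c3"))
})

test_that("malformed inputs fail with located, informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("gene\tc1\tc2", "gA\t1.0\t2.0", "gB\t3.0\toops"),
             file.path(dir, "bad.tsv"))
  expect_error(load_expression(file.path(dir, "bad.tsv")),
               "non-numeric value 'oops'.*line 3.*gB")

  writeLines(c("gene\tc1\tc2", "gA\t1\t2", "gA\t3\t4"),
             file.path(dir, "dup.tsv"))
  expect_error(load_expression(file.path(dir, "dup.tsv")),
               "duplicate gene ids")

  writeLines(c("gene\tc1\tc2", "gA\t1\t2"), file.path(dir, "ok.tsv"))
  writeLines(c("cX\t0.5", "c2\t0.1"), file.path(dir, "pt.tsv"))
  expect_error(load_expression(file.path(dir, "ok.tsv"),
                               file.path(dir, "pt.tsv")),
               "do not match")
})

test_that("MTX and dense TSV inputs yield identical expression objects", {
  dir <- withr::local_tempdir()
  set.seed(41)
  m <- matrix(rpois(30, 2), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file.path(dir, "e.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(dir, "e.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "cells.txt"))
  from_tsv <- load_expression(file.path(dir, "e.tsv"))
  from_mtx <- load_expression(file.path(dir, "e.mtx"))
  expect_equal(from_mtx$values, from_tsv$values)
})

test_that("low-expression filtering applies the floor(T/10) boundary", {
  set.seed(2)
  T_len <- 100
  base <- matrix(runif(4 * T_len, 0.1, 1), 4, T_len)
  base[1, ] <- c(rep(1, 10), rep(0, 90))   # nonzero in exactly 10 cells
  base[2, ] <- c(rep(1, 11), rep(0, 89))   # nonzero in 11 cells
  base[3, ] <- 0                           # all-zero gene
  dimnames(base) <- list(paste0("g", 1:4), paste0("c", seq_len(T_len)))
  out <- filter_low_expression(expression_matrix(base))
  expect_setequal(gene_ids(out), c("g2", "g4"))

  # surviving set equals a brute-force scan on a random matrix
  e <- tiny_expr(50, 60, seed = 11, rfun = function(n) rbinom(n, 1, 0.12))
  out2 <- filter_low_expression(e)
  keep <- vapply(seq_len(50), function(i) sum(e$values[i, ] > 0) > 6,
                 logical(1))
  expect_equal(gene_ids(out2), gene_ids(e)[keep])

  expect_error(filter_low_expression(tiny_expr(3, 5)), "at least 10 cells")
  zeros <- expression_matrix(matrix(0, 2, 20,
    dimnames = list(c("a", "b"), paste0("c", 1:20))))
  expect_error(filter_low_expression(zeros), "threshold")
})

test_that("highly variable gene selection ranks by variance with stable ties", {
  m <- rbind(g1 = c(0, 4, 0, 4), g2 = c(1, 2, 1, 2), g3 = c(3, 3, 3, 3))
  colnames(m) <- paste0("c", 1:4)
  out <- select_hvg(expression_matrix(m), 2)
  expect_equal(gene_ids(out), c("g1", "g2"))

  # tie at the cutoff: earlier gene wins
  m2 <- rbind(gA = c(0, 2), gB = c(5, 7), gC = c(9, 11))
  colnames(m2) <- c("c1", "c2")
  expect_equal(gene_ids(select_hvg(expression_matrix(m2), 2)), c("gA", "gB"))

  # brute-force variance-sort oracle on a random matrix
  e <- tiny_expr(200, 30, seed = 5)
  sel <- select_hvg(e, 50)
  v <- apply(e$values, 1, var)
  expected <- sort(names(sort(v, decreasing = TRUE)[1:50]))
  expect_setequal(gene_ids(sel), expected)
  # original order preserved among the survivors
  expect_equal(gene_ids(sel), intersect(gene_ids(e), gene_ids(sel)))

  expect_error(select_hvg(e, 0), "positive integer")
  expect_error(select_hvg(e, 201), "exceeds")
})

test_that("gold-standard filtering keeps edges with both endpoints present", {
  e <- tiny_expr(3, 12, seed = 1)  # genes g001 g002 g003
  net <- reference_network(data.frame(tf = c("g001", "g001"),
                                      target = c("g002", "gX")))
  out <- filter_gold_standard(net, e)
  expect_equal(nrow(out), 1)
  expect_equal(out$target, "g002")

  all_in <- reference_network(data.frame(tf = "g001", target = "g003"))
  expect_equal(nrow(filter_gold_standard(all_in, e)), 1)

  none <- reference_network(data.frame(tf = "x", target = "y"))
  expect_error(filter_gold_standard(none, e), "no gold-standard edge")

  # random instance vs a brute-force double-membership filter
  set.seed(8)
  genes <- sprintf("g%03d", 1:40)
  edges <- data.frame(tf = sample(genes, 60, TRUE),
                      target = sample(c(genes, "zz1", "zz2"), 60, TRUE))
  edges <- edges[edges$tf != edges$target, ]
  net2 <- reference_network(edges)
  sub <- tiny_expr(40, 12, seed = 2)
  got <- filter_gold_standard(net2, sub)
  manual <- net2[net2$tf %in% genes & net2$target %in% genes, ]
  expect_equal(nrow(got), nrow(manual))
})

test_that("reference networks drop self-loops and duplicates at load", {
  net <- reference_network(data.frame(tf = c("a", "a", "b", "c"),
                                      target = c("b", "b", "a", "c")))
  expect_equal(nrow(net), 2)  # dup (a,b) collapsed, self-loop (c,c) dropped
  expect_true(all(net$tf != net$target))
})

test_that("balanced pair sampling is seeded, disjoint from gold, 1:1", {
  e <- tiny_expr(5, 12, seed = 3)
  gold <- reference_network(data.frame(
    tf = c("g001", "g001", "g002"), target = c("g002", "g003", "g004")))
  s1 <- build_pair_samples(gold, e, seed = 9)
  s2 <- build_pair_samples(gold, e, seed = 9)
  expect_identical(s1, s2)
  expect_equal(sum(s1$label == 1), 3)
  expect_equal(sum(s1$label == 0), 3)
  neg <- s1[s1$label == 0, ]
  expect_true(all(neg$tf %in% c("g001", "g002")))  # regulators only
  expect_true(all(neg$tf != neg$target))

  # no negative ever collides with a gold edge, across many seeds
  gold_key <- paste(gold$tf, gold$target)
  for (seed in 1:100) {
    neg_s <- subset(build_pair_samples(gold, e, seed = seed), label == 0)
    expect_false(any(paste(neg_s$tf, neg_s$target) %in% gold_key))
  }

  # candidate pool too small: 1 TF, 3 genes, both non-self pairs are gold
  e3 <- tiny_expr(3, 12, seed = 4)
  g3 <- reference_network(data.frame(tf = c("g001", "g001"),
                                     target = c("g002", "g003")))
  expect_error(build_pair_samples(g3, e3, seed = 1), "candidate pool")
})

test_that("stratified 3:1:1 split partitions both classes proportionally", {
  mk <- function(n_pos, n_neg) {
    structure(data.frame(
      tf = paste0("t", seq_len(n_pos + n_neg)),
      target = paste0("g", seq_len(n_pos + n_neg)),
      label = rep(c(1L, 0L), c(n_pos, n_neg))),
      class = c("lagnet_pairs", "data.frame"))
  }
  sp <- split_samples(mk(50, 50), seed = 1)
  expect_equal(vapply(sp, nrow, 1L), c(train = 60L, val = 20L, test = 20L))
  expect_equal(vapply(sp, function(s) sum(s$label), 1L),
               c(train = 30L, val = 10L, test = 10L))

  # partition property + per-class proportion audit on random sizes
  set.seed(21)
  for (rep in 1:50) {
    n_pos <- sample(5:40, 1); n_neg <- sample(5:40, 1)
    s <- mk(n_pos, n_neg)
    sp <- split_samples(s, seed = rep)
    joined <- do.call(rbind, lapply(sp, as.data.frame))
    expect_equal(nrow(joined), nrow(s))
    expect_false(any(duplicated(joined$tf)))
    for (part in sp) {
      frac <- nrow(part) / nrow(s)
      expect_lte(abs(sum(part$label) - frac * n_pos), 1 + 1e-9)
    }
  }
  expect_error(split_samples(mk(4, 10), seed = 1), "at least 5")
})

test_that("the preprocessing chain leaves no pair gene outside the matrix", {
  set.seed(33)
  for (rep in 1:5) {
    e <- tiny_expr(30, 50, seed = rep,
                   rfun = function(n) rbinom(n, 4, 0.4) * runif(n))
    genes <- gene_ids(e)
    edges <- unique(data.frame(tf = sample(genes[1:6], 25, TRUE),
                               target = sample(genes, 25, TRUE)))
    edges <- edges[edges$tf != edges$target, ][1:12, ]
    gold <- reference_network(edges)
    ef <- select_hvg(filter_low_expression(e), 20)
    gf <- try(filter_gold_standard(gold, ef), silent = TRUE)
    if (inherits(gf, "try-error")) next
    if (nrow(gf) < 1) next
    ps <- try(build_pair_samples(gf, ef, seed = rep), silent = TRUE)
    if (inherits(ps, "try-error")) next
    expect_true(all(c(ps$tf, ps$target) %in% gene_ids(ef)))
  }
})
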