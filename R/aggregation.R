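#' Configuration for correlated-neighbor aggregation
#'
#' Expression smoothing replaces each gene's vector by the mean of its `k`
#' most similar genes' vectors.  Similarity defaults to the Pearson
#' correlation across cells; Spearman, Kendall and a binned mutual
#' information estimator are available as alternatives (in practice the
#' neighbor sets, and hence the aggregates, are nearly interchangeable on
#' smooth trajectory data).
#'
#' @param k Number of neighbor genes to average (1 <= k <= genes - 1).
#'   Default 10, a mid-range choice: small enough to avoid averaging in
#'   unrelated genes, large enough to suppress per-gene noise.
#' @param similarity One of `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"mutual_information"`.
#' @param include_self Include gene i itself among its own neighbors?  The
#'   default `FALSE` excludes it: self-similarity is trivially maximal and
#'   including it would dilute the smoothing the step exists for.
#' @return A list of class `lagnet_agg_config`.
#' @export
aggregation_config <- function(k = 10,
                               similarity = c("pearson", "spearman",
                                              "kendall", "mutual_information"),
                               include_self = FALSE) {
  similarity <- match.arg(similarity)
  if (!is_count(k)) stop("`k` must be a positive integer")
  structure(list(k = as.integer(k), similarity = similarity,
                 include_self = isTRUE(include_self)),
            class = "lagnet_agg_config")
}

#' Gene-by-gene similarity matrix
#'
#' Symmetric matrix of pairwise similarities between gene expression vectors
#' across cells.  Zero-variance genes get similarity 0 to every other gene
#' (their correlation is undefined; 0 is the neutral "no signal" value).  The
#' diagonal holds the measure's self-value but is never used for neighbor
#' selection.
#'
#' @param expr A [expression_matrix()] object with at least 3 cells.
#' @param cfg An [aggregation_config()].
#' @return A genes-by-genes numeric matrix with gene ids as dimnames.
#' @export
similarity_matrix <- function(expr, cfg = aggregation_config()) {
  stopifnot(inherits(expr, "lagnet_expr"), inherits(cfg, "lagnet_agg_config"))
  v <- expr$values
  if (ncol(v) < 3) stop("similarity requires at least 3 cells")
  constant <- matrixStats_rowVars(v) == 0
  if (cfg$similarity %in% c("pearson", "spearman", "kendall")) {
    s <- suppressWarnings(stats::cor(t(v), method = cfg$similarity))
    s[is.na(s)] <- 0
    diag(s) <- ifelse(constant, 0, 1)
  } else {
    s <- mutual_information_matrix(v)
    s[constant, ] <- 0
    s[, constant] <- 0
  }
  dimnames(s) <- list(rownames(v), rownames(v))
  s
}

# Mutual information from equal-width binning with ceiling(sqrt(T)) bins.
mutual_information_matrix <- function(v) {
  n_bins <- ceiling(sqrt(ncol(v)))
  binned <- t(apply(v, 1, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(1L, length(x)))
    b <- findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1),
                      rightmost.closed = TRUE, all.inside = TRUE)
    as.integer(b)
  }))
  g <- nrow(v)
  s <- matrix(0, g, g)
  for (i in seq_len(g)) {
    for (j in i:g) {
      tab <- table(binned[i, ], binned[j, ])
      p <- tab / sum(tab)
      px <- rowSums(p); py <- colSums(p)
      nz <- p > 0
      mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
      s[i, j] <- s[j, i] <- mi
    }
  }
  s
}

#' Smooth expression by averaging correlated neighbors
#'
#' For each gene i, the output vector is the per-cell mean of the expression
#' vectors of its `k` highest-similarity genes (excluding i itself unless
#' configured otherwise).  Ties at the k-th rank are broken stably by gene
#' order.  Shape, gene order and cell order are preserved.
#'
#' @inheritParams similarity_matrix
#' @return A new [expression_matrix()] with the same dimensions and ids.
#' @export
aggregate_expression <- function(expr, cfg = aggregation_config()) {
  stopifnot(inherits(expr, "lagnet_expr"), inherits(cfg, "lagnet_agg_config"))
  v <- expr$values
  g <- nrow(v)
  max_k <- if (cfg$include_self) g else g - 1
  if (cfg$k > max_k) {
    stop("`k` (", cfg$k, ") exceeds the number of candidate neighbors (",
         max_k, ")")
  }
  s <- similarity_matrix(expr, cfg)
  out <- v
  for (i in seq_len(g)) {
    si <- s[i, ]
    if (!cfg$include_self) si[i] <- -Inf
    nb <- order(-si)[seq_len(cfg$k)]  # stable: ties keep gene order
    out[i, ] <- colMeans(v[nb, , drop = FALSE])
  }
  expression_matrix(out, pseudotime = expr$pseudotime)
}
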