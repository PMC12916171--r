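#' Configuration for the planted-edge synthetic benchmark
#'
#' The generator emulates the structure the delay-matrix machinery assumes:
#' each transcription factor follows a smooth latent trajectory (a sum of
#' low-frequency sinusoids with random phases and amplitudes), each planted
#' edge makes the target reproduce its regulator's signal shifted right by a
#' lag, and decoy genes carry independent smooth signals.  Additive Gaussian
#' noise is applied to every gene, and all values are shifted to be
#' nonnegative.  Pseudotime is simply the cell index `1..T`.
#'
#' Each planted target is driven by exactly one TF (targets are sampled
#' without replacement), so the true lag of every edge is unambiguous; this
#' requires `n_edges <= n_genes - n_tfs`.
#'
#' @param n_genes Total number of genes (TFs + targets + decoys).
#' @param n_cells Trajectory length T.
#' @param n_tfs Number of transcription factors.
#' @param n_edges Number of planted TF -> target edges.
#' @param lag_range Integer interval (cells) the true lags are drawn from;
#'   the maximum lag may not exceed `T/4`.
#' @param effect Multiplier applied to the lagged TF signal in its target.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (the latent signals have unit standard deviation).
#' @param smoothness Length scale of the latent signals, in cells: the
#'   shortest sinusoid wavelength used.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A list of class `lagnet_synth_config`.
#' @export
synthetic_config <- function(n_genes = 60, n_cells = 600, n_tfs = 10,
                             n_edges = 30, lag_range = c(5, 40), effect = 1,
                             noise_sd = 0.5, smoothness = 50, seed = 7) {
  stopifnot(is_count(n_genes), is_count(n_cells), is_count(n_tfs),
            is_count(n_edges), is.numeric(lag_range), length(lag_range) == 2)
  lag_range <- as.integer(lag_range)
  if (lag_range[1] < 0 || lag_range[1] > lag_range[2]) {
    stop("`lag_range` must be a nondecreasing nonnegative integer interval")
  }
  if (lag_range[2] > n_cells / 4) {
    stop("maximum lag (", lag_range[2], ") exceeds T/4 = ", n_cells / 4)
  }
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (n_tfs >= n_genes) stop("`n_tfs` must be smaller than `n_genes`")
  if (n_edges > n_genes - n_tfs) {
    stop("infeasible edge count: each planted target is driven by one TF, ",
         "so n_edges (", n_edges, ") may not exceed n_genes - n_tfs (",
         n_genes - n_tfs, ")")
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 n_tfs = as.integer(n_tfs), n_edges = as.integer(n_edges),
                 lag_range = lag_range, effect = effect, noise_sd = noise_sd,
                 smoothness = smoothness, seed = as.integer(seed)),
            class = "lagnet_synth_config")
}

# Smooth unit-variance latent signal: 3 sinusoids with wavelengths >= L.
smooth_signal <- function(T_len, L) {
  t <- seq_len(T_len)
  n_comp <- 3L
  cycles <- stats::runif(n_comp, 1, max(1.5, T_len / L))
  amp <- stats::runif(n_comp, 0.5, 1)
  phase <- stats::runif(n_comp, 0, 2 * pi)
  s <- rowSums(vapply(seq_len(n_comp), function(j) {
    amp[j] * sin(2 * pi * cycles[j] * t / T_len + phase[j])
  }, numeric(T_len)))
  (s - mean(s)) / stats::sd(s)
}

# Right-shift with constant padding: the first `lag` positions repeat x[1].
shift_pad <- function(x, lag) {
  if (lag == 0) return(x)
  c(rep(x[1], lag), x[seq_len(length(x) - lag)])
}

#' Simulate a pseudotime trajectory with planted time-lagged edges
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `expr` (a [expression_matrix()] with pseudotime
#'   `1..T`), `network` (a [reference_network()] of the planted edges,
#'   labelled `"gold"`), and `lags` (data frame `tf`, `target`, `lag` of the
#'   true lags).
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "lagnet_synth_config"))
  with_seed(cfg$seed, {
    T_len <- cfg$n_cells
    tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    other <- sprintf("G%03d", seq_len(cfg$n_genes - cfg$n_tfs))
    genes <- c(tf_names, other)
    latent <- vapply(tf_names, function(g) smooth_signal(T_len, cfg$smoothness),
                     numeric(T_len))
    targets <- sample(other, cfg$n_edges)
    edge_tf <- sample(tf_names, cfg$n_edges, replace = TRUE)
    lag_pool <- seq(cfg$lag_range[1], cfg$lag_range[2])
    lags <- lag_pool[sample.int(length(lag_pool), cfg$n_edges,
                                replace = TRUE)]  # safe for length-1 pools
    vals <- matrix(0, cfg$n_genes, T_len, dimnames = list(genes, NULL))
    for (i in seq_len(cfg$n_tfs)) {
      vals[tf_names[i], ] <- latent[, i]
    }
    for (e in seq_len(cfg$n_edges)) {
      vals[targets[e], ] <-
        cfg$effect * shift_pad(latent[, edge_tf[e]], lags[e])
    }
    decoys <- setdiff(other, targets)
    for (g in decoys) {
      vals[g, ] <- smooth_signal(T_len, cfg$smoothness)
    }
    if (cfg$noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(length(vals), sd = cfg$noise_sd),
                            nrow(vals), ncol(vals))
    }
    vals <- vals - min(vals)  # one global shift keeps signals comparable
    colnames(vals) <- sprintf("cell%04d", seq_len(T_len))
    expr <- expression_matrix(vals,
                              pseudotime = stats::setNames(seq_len(T_len),
                                                           colnames(vals)))
    net <- reference_network(
      data.frame(tf = edge_tf, target = targets, stringsAsFactors = FALSE),
      label = "gold")
    list(expr = expr, network = net,
         lags = data.frame(tf = edge_tf, target = targets, lag = lags,
                           stringsAsFactors = FALSE))
  })
}

#' Write a pipeline-ready synthetic benchmark to disk
#'
#' Materializes [simulate_dataset()] in the package's on-disk input formats:
#' `expression.tsv` (genes x cells), `pseudotime.tsv` (cell, pseudotime),
#' `gold.tsv` (tf, target) and `manifest.json` (configuration plus the true
#' lags).  Loading the files back through [load_expression()] and
#' [load_network()] reproduces the in-memory objects.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list returned by [simulate_dataset()] with an
#'   added `paths` element.
#' @export
make_benchmark <- function(cfg = synthetic_config(), dir) {
  stopifnot(inherits(cfg, "lagnet_synth_config"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create benchmark directory: ", dir)
  }
  sim <- simulate_dataset(cfg)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    pseudotime = file.path(dir, "pseudotime.tsv"),
    gold = file.path(dir, "gold.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_expression(sim$expr, paths$expression, paths$pseudotime)
  utils::write.table(sim$network[, c("tf", "target")], paths$gold,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), lags = sim$lags),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}
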