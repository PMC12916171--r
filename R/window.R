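#' Sliding-window geometry for delay-correlation matrices
#'
#' A window configuration fixes the geometry of the time-delay correlation
#' matrix: `p` TF windows (rows), `q` delay offsets (columns), TF window step
#' `m`, delay step `n`, and window width `w`, all in cells along the
#' pseudotime axis.  The k-th TF segment covers cells `(k-1)m+1 .. (k-1)m+w`;
#' the target segment at delay l covers `(k-1)m+(l-1)n+1 .. (k-1)m+(l-1)n+w`,
#' i.e. the target lags the TF by `(l-1)n` cells.
#'
#' @param p,q Number of TF windows / delay offsets (positive integers).
#' @param m,n TF window step / delay step in cells (positive integers).
#' @param w Window width in cells (at least 3).
#' @return A list of class `lagnet_window`.
#' @export
window_config <- function(p, q, m, n, w) {
  for (nm in c("p", "q", "m", "n", "w")) {
    val <- get(nm)
    if (!is_count(val)) stop("`", nm, "` must be a positive integer")
  }
  if (w < 3) stop("window width `w` must be at least 3")
  structure(list(p = as.integer(p), q = as.integer(q), m = as.integer(m),
                 n = as.integer(n), w = as.integer(w)),
            class = "lagnet_window")
}

#' @export
print.lagnet_window <- function(x, ...) {
  cat(sprintf("<lagnet_window> p=%d q=%d m=%d n=%d w=%d (requires T >= %d)\n",
              x$p, x$q, x$m, x$n, x$w, required_cells(x)))
  invisible(x)
}

#' Segment index ranges for one matrix entry
#'
#' Returns the 1-based inclusive cell ranges of the TF segment for window
#' index `k` and of the target segment at delay index `l`.
#'
#' @param k TF window index in `1..p`.
#' @param l Delay index in `1..q`.
#' @param cfg A [window_config()].
#' @return A list with integer vectors `tf = c(start, end)` and
#'   `target = c(start, end)`; both spans have length `w` and the target
#'   lags the TF by `(l-1)*n` cells.
#' @export
segment_bounds <- function(k, l, cfg) {
  stopifnot(inherits(cfg, "lagnet_window"))
  if (!is_count(k) || k > cfg$p) stop("`k` must be in 1..p")
  if (!is_count(l) || l > cfg$q) stop("`l` must be in 1..q")
  tf_start <- (k - 1L) * cfg$m + 1L
  tg_start <- tf_start + (l - 1L) * cfg$n
  list(tf = c(tf_start, tf_start + cfg$w - 1L),
       target = c(tg_start, tg_start + cfg$w - 1L))
}

#' Minimal trajectory length for a window configuration
#'
#' The number of pseudotime-ordered cells needed so that every one of the
#' `p * q` segment pairs fits: `(p-1)m + (q-1)n + w`, the end of the last
#' target segment (k = p, l = q).
#'
#' @param cfg A [window_config()].
#' @return A positive integer cell count.
#' @export
required_cells <- function(cfg) {
  stopifnot(inherits(cfg, "lagnet_window"))
  (cfg$p - 1L) * cfg$m + (cfg$q - 1L) * cfg$n + cfg$w
}

#' Solve a window configuration for a given trajectory length
#'
#' Chooses the largest window width that uses the whole trajectory,
#' `w = T - (p-1)m - (q-1)n`.  If that width falls below 3 the grid is
#' coarsened by halving `p` and `q` until feasible (logged); if no grid with
#' `p = q = 1` fits, an error reports the minimal usable T.
#'
#' @param T Number of cells along the trajectory.
#' @param p,q Desired matrix dimensions (default 64 x 64).
#' @param m,n Window and delay steps in cells (default 5).
#' @param verbose Log grid adjustments?
#' @return A [window_config()] with `required_cells(cfg) <= T`.
#' @export
default_window_config <- function(T, p = 64, q = 64, m = 5, n = 5,
                                  verbose = FALSE) {
  if (!is_count(T)) stop("`T` must be a positive integer")
  if (T < 3) stop("trajectory too short: need at least 3 cells, have ", T)
  p0 <- p; q0 <- q
  repeat {
    w <- T - (p - 1) * m - (q - 1) * n
    if (w >= 3) break
    if (p <= 1 && q <= 1) {
      stop("no feasible window configuration: need at least ",
           (p0 - 1) * m + (q0 - 1) * n + 3, " cells for a ", p0, "x", q0,
           " grid (have ", T, ")")
    }
    p <- max(1, floor(p / 2)); q <- max(1, floor(q / 2))
  }
  if (p != p0 || q != q0) {
    vlog(verbose, sprintf("window grid reduced from %dx%d to %dx%d to fit T=%d",
                          p0, q0, p, q, T))
  }
  window_config(p, q, m, n, w)
}

#' Published per-dataset window presets
#'
#' Window widths (and, for the short hHep trajectory, steps) used for the
#' benchmark datasets this method was developed on.  `p` and `q` are solved
#' from the actual trajectory length at use time via
#' [default_window_config()].
#'
#' @return A data frame with columns `dataset`, `w`, `m`, `n`.
#' @export
window_presets <- function() {
  data.frame(
    dataset = c("mHSC-E", "mHSC-L", "mHSC-GM", "hESC", "hHep"),
    w = c(441L, 217L, 259L, 128L, 173L),
    m = c(5L, 5L, 5L, 5L, 2L),
    n = c(5L, 5L, 5L, 5L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Build the time-delay correlation matrix for one gene pair
#'
#' Entry (k, l) is the Pearson correlation between the TF segment of window k
#' and the target segment lagged by `(l-1)n` cells (see [segment_bounds()]).
#' Segments with zero variance yield correlation 0 rather than `NaN` --
#' a constant segment carries no signal, and finite matrices are required by
#' the enhancement stage.  Entries are clamped to `[-1, 1]` against rounding.
#'
#' @param tf_row,target_row Numeric vectors of length `T >=
#'   required_cells(cfg)`: the (optionally aggregated) expression of the TF
#'   and candidate target along the trajectory.
#' @param cfg A [window_config()].
#' @param tf_id,target_id Optional gene identifiers carried in the result.
#' @return An object of class `lagnet_delay`: list with `values` (p x q
#'   matrix), `tf_id`, `target_id` and `config`.
#' @export
build_delay_matrix <- function(tf_row, target_row, cfg,
                               tf_id = NA_character_,
                               target_id = NA_character_) {
  stopifnot(inherits(cfg, "lagnet_window"))
  T_len <- length(tf_row)
  if (length(target_row) != T_len) {
    stop("tf_row and target_row must have equal length")
  }
  need <- required_cells(cfg)
  if (T_len < need) {
    stop("trajectory too short: configuration requires ", need,
         " cells, vectors have ", T_len)
  }
  p <- cfg$p; q <- cfg$q; w <- cfg$w
  M <- matrix(0, p, q)
  # Gather all q lagged target segments for one TF window at a time and
  # correlate them against the fixed TF segment in a single vectorized pass.
  off <- outer(seq_len(w) - 1L, (seq_len(q) - 1L) * cfg$n, "+")
  for (k in seq_len(p)) {
    a <- (k - 1L) * cfg$m + 1L
    x <- tf_row[a:(a + w - 1L)]
    seg <- matrix(target_row[a + off], nrow = w)
    xc <- x - mean(x)
    sc <- sweep(seg, 2, colMeans(seg))
    sx <- sqrt(sum(xc * xc))
    sy <- sqrt(colSums(sc * sc))
    denom <- sx * sy
    r <- ifelse(denom > 0, colSums(xc * sc) / denom, 0)
    M[k, ] <- pmin(1, pmax(-1, r))
  }
  structure(list(values = M, tf_id = tf_id, target_id = target_id,
                 config = cfg),
            class = "lagnet_delay")
}

#' @export
print.lagnet_delay <- function(x, ...) {
  cat(sprintf("<lagnet_delay> %s -> %s: %dx%d, range [%.3f, %.3f]\n",
              x$tf_id, x$target_id, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Plot a delay-correlation (or enhanced) matrix as a heatmap
#'
#' Rows are TF windows (window 1 at the top), columns delay offsets.  For
#' delay matrices the color scale is fixed to `[-1, 1]`; enhanced matrices
#' use `[0, max]`.
#'
#' @param M A `lagnet_delay` or `lagnet_enhanced` object.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @return Invisibly, `path`.
#' @export
plot_delay_heatmap <- function(M, path, width = 480, height = 480) {
  if (inherits(M, "lagnet_delay")) {
    v <- M$values
    if (any(v < -1 | v > 1)) {
      stop("delay matrix entries outside [-1, 1]; invalid object")
    }
    zlim <- c(-1, 1)
    cols <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(101)
  } else if (inherits(M, "lagnet_enhanced")) {
    v <- M$values
    zlim <- c(0, max(v, 1e-12))
    cols <- grDevices::colorRampPalette(c("#FFFFFF", "#B2182B"))(101)
  } else {
    stop("`M` must be a lagnet_delay or lagnet_enhanced object")
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::image(
    x = seq_len(ncol(v)), y = seq_len(nrow(v)),
    z = t(v[nrow(v):1, , drop = FALSE]),
    zlim = zlim, col = cols, useRaster = TRUE,
    xlab = "delay offset index (l)", ylab = "TF window index (k)",
    main = sprintf("%s → %s", M$tf_id, M$target_id), yaxt = "n")
  at <- pretty(seq_len(nrow(v)))
  at <- at[at >= 1 & at <= nrow(v)]
  graphics::axis(2, at = nrow(v) + 1 - at, labels = at)
  invisible(path)
}
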