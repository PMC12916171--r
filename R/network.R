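#' Construct a directed reference network
#'
#' A set of directed TF -> target edges with a short category label (for
#' example `"gold"` for the training gold standard, or the name of an
#' orthogonal resource used only to annotate exported edges).  Duplicate
#' edges are collapsed and self-loops are dropped (with a log line), since a
#' self-regulating pair carries no usable time-delay signal here.
#'
#' @param edges A data frame whose first two columns are TF and target gene
#'   identifiers (extra columns are preserved).
#' @param label Short category name for the network.
#' @param verbose Log dropped self-loops / duplicates?
#' @return An object of class `lagnet_network`: a data frame with columns
#'   `tf` and `target` (plus any extras) and attribute `label`.
#' @export
reference_network <- function(edges, label = "gold", verbose = FALSE) {
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    stop("`edges` must be a data frame with at least two columns (tf, target)")
  }
  df <- edges
  names(df)[1:2] <- c("tf", "target")
  df$tf <- as.character(df$tf)
  df$target <- as.character(df$target)
  loops <- df$tf == df$target
  if (any(loops)) {
    vlog(verbose, sprintf("dropped %d self-loop(s)", sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  dup <- duplicated(df[, c("tf", "target")])
  if (any(dup)) {
    vlog(verbose, sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("lagnet_network", "data.frame"), label = label)
}

#' @export
print.lagnet_network <- function(x, ...) {
  cat(sprintf("<lagnet_network> '%s': %d directed edges, %d regulators\n",
              attr(x, "label"), nrow(x), length(unique(x$tf))))
  invisible(x)
}

#' Load a reference network from a TSV file
#'
#' Expects at least two columns (TF, target); extra columns are ignored for
#' edge identity but retained.  A header line is detected heuristically.
#'
#' @param path Path to the edge-list TSV.
#' @inheritParams reference_network
#' @return A [reference_network()] object.
#' @export
load_network <- function(path, label = "gold", verbose = FALSE) {
  if (!file.exists(path)) stop("network file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  if (ncol(tab) < 2) stop("network table must have at least two columns")
  first <- tolower(as.character(tab[1, 1:2]))
  if (any(first %in% c("tf", "regulator", "source", "gene1", "from"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  reference_network(tab, label = label, verbose = verbose)
}

#' Restrict a gold standard to the working gene set
#'
#' Keeps only edges whose TF and target both appear in the expression
#' matrix's gene list (the post-filtering, highly-variable working set).
#'
#' @param net A [reference_network()] object.
#' @param expr A [expression_matrix()] object defining the working genes.
#' @param verbose Log kept/dropped counts?
#' @return The filtered `lagnet_network`.
#' @export
filter_gold_standard <- function(net, expr, verbose = FALSE) {
  stopifnot(inherits(net, "lagnet_network"), inherits(expr, "lagnet_expr"))
  genes <- gene_ids(expr)
  keep <- net$tf %in% genes & net$target %in% genes
  vlog(verbose, sprintf("gold standard: kept %d / %d edges on %d genes",
                        sum(keep), length(keep), length(genes)))
  if (!any(keep)) {
    stop("no gold-standard edge has both endpoints in the working gene set; ",
         "nothing to learn from")
  }
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(net), label = attr(net, "label"))
}

#' Build a balanced labelled pair set
#'
#' Positives are all edges of the (already gene-filtered) gold standard.
#' Negatives are an equal-sized uniform sample, without replacement, from all
#' pairs (tf, g) where `tf` appears as a regulator in the gold standard,
#' `g` is any other working gene, and (tf, g) is not a gold edge.  Sampling
#' is deterministic for a fixed seed.
#'
#' @param gold A [reference_network()] filtered to `expr`'s genes.
#' @param expr A [expression_matrix()] object.
#' @param seed Integer seed for negative sampling.
#' @return A data frame of class `lagnet_pairs` with columns `tf`, `target`,
#'   `label` (1 = gold edge, 0 = sampled non-edge).
#' @export
build_pair_samples <- function(gold, expr, seed = 1) {
  stopifnot(inherits(gold, "lagnet_network"), inherits(expr, "lagnet_expr"))
  genes <- gene_ids(expr)
  if (!all(gold$tf %in% genes) || !all(gold$target %in% genes)) {
    stop("gold standard contains genes outside the expression matrix; ",
         "run filter_gold_standard() first")
  }
  n_pos <- nrow(gold)
  if (n_pos < 1) stop("gold standard has no edges")
  tfs <- unique(gold$tf)
  cand <- expand.grid(tf = tfs, target = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- cand[cand$tf != cand$target, , drop = FALSE]
  gold_key <- paste(gold$tf, gold$target, sep = "\r")
  cand <- cand[!(paste(cand$tf, cand$target, sep = "\r") %in% gold_key), ,
               drop = FALSE]
  if (nrow(cand) < n_pos) {
    stop("negative candidate pool (", nrow(cand),
         " pairs) is smaller than the number of positives (", n_pos, ")")
  }
  neg_idx <- with_seed(seed, sample.int(nrow(cand), n_pos))
  out <- rbind(
    data.frame(tf = gold$tf, target = gold$target, label = 1L,
               stringsAsFactors = FALSE),
    data.frame(tf = cand$tf[neg_idx], target = cand$target[neg_idx],
               label = 0L, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("lagnet_pairs", "data.frame")
  out
}

#' Stratified train / validation / test split
#'
#' Splits the labelled pair set 3:1:1 (fractions 0.6 / 0.2 / 0.2) separately
#' within each class so class proportions are preserved; per-class remainders
#' are assigned train-first, then validation.  Assignment within a class is a
#' seeded shuffle, so the split is deterministic for a fixed seed.
#'
#' @param samples A `lagnet_pairs` data frame (see [build_pair_samples()]).
#' @param seed Integer seed for the shuffles.
#' @return A list with elements `train`, `val`, `test`, each a `lagnet_pairs`
#'   data frame; the three are disjoint and exhaustive.
#' @export
split_samples <- function(samples, seed = 1) {
  stopifnot(is.data.frame(samples), all(c("tf", "target", "label") %in% names(samples)))
  counts <- table(factor(samples$label, levels = c(0, 1)))
  if (any(counts < 5)) {
    stop("each class needs at least 5 samples for a stratified 3:1:1 split ",
         "(have ", counts[["1"]], " positives, ", counts[["0"]], " negatives)")
  }
  assign_split <- function(n) {
    n_tr <- floor(0.6 * n); n_va <- floor(0.2 * n); n_te <- floor(0.2 * n)
    rem <- n - n_tr - n_va - n_te
    if (rem >= 1) n_tr <- n_tr + 1         # remainders go train-first
    if (rem >= 2) n_va <- n_va + 1
    rep(c("train", "val", "test"), c(n_tr, n_va, n_te))
  }
  grp <- character(nrow(samples))
  with_seed(seed, {
    for (cls in c(1, 0)) {
      idx <- which(samples$label == cls)
      grp[sample(idx)] <- assign_split(length(idx))
    }
  })
  out <- lapply(c(train = "train", val = "val", test = "test"), function(g) {
    sub <- samples[grp == g, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("lagnet_pairs", "data.frame")
    sub
  })
  out
}
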