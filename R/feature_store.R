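#' Featurize labelled gene pairs
#'
#' Turns each candidate pair into its p x q matrix: the time-delay
#' correlation matrix of the (optionally aggregated) TF and target rows,
#' optionally passed through [enhance()].
#'
#' @param pairs A `lagnet_pairs` data frame (`tf`, `target`, `label`).
#' @param expr A [expression_matrix()] object (aggregated or raw).
#' @param window A [window_config()].
#' @param enhanced Apply the dual-background standardization?
#' @param combine,ddof Passed to [enhance()] when `enhanced = TRUE`.
#' @return A list of `lagnet_enhanced` (or `lagnet_delay`) objects, one per
#'   row of `pairs`, in order.
#' @export
featurize_pairs <- function(pairs, expr, window, enhanced = TRUE,
                            combine = "euclidean", ddof = 0) {
  stopifnot(is.data.frame(pairs), inherits(expr, "lagnet_expr"),
            inherits(window, "lagnet_window"))
  v <- expr$values
  missing_genes <- setdiff(unique(c(pairs$tf, pairs$target)), rownames(v))
  if (length(missing_genes)) {
    stop("pairs reference genes absent from the expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  lapply(seq_len(nrow(pairs)), function(i) {
    M <- build_delay_matrix(v[pairs$tf[i], ], v[pairs$target[i], ], window,
                            tf_id = pairs$tf[i], target_id = pairs$target[i])
    if (enhanced) enhance(M, combine = combine, ddof = ddof) else M
  })
}

#' Write featurized pairs to a directory
#'
#' Stores one TSV grid per pair plus an `index.tsv` (pair id, tf, target,
#' label, enhanced flag, file name), the on-disk interchange format between
#' the `featurize` and `train`/`predict` command-line steps.
#'
#' @param features List of `lagnet_delay`/`lagnet_enhanced` objects.
#' @param pairs The matching `lagnet_pairs` data frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_feature_store <- function(features, pairs, dir) {
  stopifnot(length(features) == nrow(pairs))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  enhanced <- vapply(features, inherits, TRUE, what = "lagnet_enhanced")
  files <- sprintf("pair%05d.tsv", seq_along(features))
  for (i in seq_along(features)) {
    utils::write.table(features[[i]]$values, file.path(dir, files[i]),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  idx <- data.frame(pair_id = seq_along(features), tf = pairs$tf,
                    target = pairs$target, label = pairs$label,
                    enhanced = enhanced, file = files,
                    stringsAsFactors = FALSE)
  utils::write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a featurized-pair directory
#'
#' @param dir Directory written by [write_feature_store()].
#' @return A list with `pairs` (data frame incl. labels) and `matrices`
#'   (list of plain numeric matrices, in index order).
#' @export
read_feature_store <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  if (!file.exists(idx_path)) stop("no index.tsv in ", dir)
  idx <- utils::read.table(idx_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  mats <- lapply(idx$file, function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t", header = FALSE))
  })
  mats <- lapply(mats, function(m) {
    dimnames(m) <- NULL
    m
  })
  list(pairs = idx, matrices = mats)
}
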