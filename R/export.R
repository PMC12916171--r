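#' Export the predicted regulatory network
#'
#' Ranks scored candidate pairs in descending score order, keeps the top E
#' pairs where E equals the number of gold-standard edges (so the predicted
#' network has the same edge budget as the known one), and annotates each
#' kept edge with a category: `"known"` if it is a gold edge, otherwise the
#' label of the first supplied reference network containing it (in the order
#' given), otherwise `"novel"`.  Ties at the cutoff are broken by
#' (score, tf, target) lexicographic order so the export is deterministic.
#'
#' @param scores A data frame with columns `tf`, `target`, `score`.
#' @param gold A [reference_network()] gold standard (nonempty).
#' @param refs Optional list of additional [reference_network()] objects,
#'   in category priority order (e.g. cell-type-specific before
#'   protein-interaction).
#' @param path Optional output TSV path.
#' @return A data frame with columns `tf`, `target`, `score`, `category`,
#'   exactly E rows, ordered by decreasing score.
#' @export
export_grn <- function(scores, gold, refs = list(), path = NULL) {
  stopifnot(is.data.frame(scores),
            all(c("tf", "target", "score") %in% names(scores)),
            inherits(gold, "lagnet_network"))
  E <- nrow(gold)
  if (E < 1) stop("gold standard is empty")
  if (nrow(scores) < E) {
    stop("only ", nrow(scores), " scored pairs but ", E,
         " edges requested (|gold|)")
  }
  ord <- order(-scores$score, scores$tf, scores$target)
  top <- scores[ord[seq_len(E)], c("tf", "target", "score")]
  key <- function(df) paste(df$tf, df$target, sep = "\r")
  category <- rep("novel", E)
  for (i in rev(seq_along(refs))) {
    ref <- refs[[i]]
    stopifnot(inherits(ref, "lagnet_network"))
    hit <- key(top) %in% key(ref)
    category[hit] <- attr(ref, "label") %||% paste0("ref", i)
  }
  category[key(top) %in% key(gold)] <- "known"
  top$category <- category
  rownames(top) <- NULL
  if (!is.null(path)) {
    utils::write.table(top, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  top
}
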