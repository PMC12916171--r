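#' Ranking metrics for scored gene pairs
#'
#' Computes the standard threshold-free metrics for supervised edge
#' prediction plus the early-retrieval summaries commonly used for GRN
#' benchmarks:
#'
#' * AUROC via the rank-sum statistic (ties handled with midranks);
#' * AUPR via step-wise precision-recall integration (average precision),
#'   with tied scores processed as one block;
#' * Precision at k for each requested k (ranking ties broken stably);
#' * early precision: precision among the top-P ranked pairs, where P is the
#'   number of positives;
#' * the FDR-controlled subnetwork size: the largest top-ranked prefix whose
#'   empirical precision is at least `1 - alpha`;
#' * the confusion matrix at a fixed score threshold.
#'
#' @param scores Numeric prediction scores, higher = more likely an edge.
#' @param labels Binary labels (0/1), same length as `scores`.
#' @param k_values Integer vector of cutoffs for precision at k; values
#'   exceeding the number of pairs are dropped.
#' @param alpha FDR level for the subnetwork size (default 0.05).
#' @param threshold Score threshold for the confusion counts (default 0.5).
#' @return A list of class `lagnet_eval` with elements `auroc`, `aupr`,
#'   `precision_at_k` (named numeric), `early_precision`,
#'   `fdr_subnetwork_size`, `confusion` (TP, FP, TN, FN) and `n`.
#' @export
compute_metrics <- function(scores, labels, k_values = c(10L, 25L, 50L, 100L),
                            alpha = 0.05, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (anyNA(scores) || anyNA(labels) || any(!is.finite(scores))) {
    stop("scores and labels must be finite and non-missing")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0 || N == 0) {
    stop("both classes must be present (have ", P, " positives, ",
         N, " negatives)")
  }
  # AUROC: Mann-Whitney with midranks.
  r <- rank(scores)  # average ranks on ties
  auroc <- (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
  # Ranking, ties grouped at distinct score values.
  ord <- order(-scores)
  lab_sorted <- labels[ord]
  sc_sorted <- scores[ord]
  cum_tp <- cumsum(lab_sorted)
  idx <- seq_along(lab_sorted)
  block_end <- idx[c(sc_sorted[-1] != sc_sorted[-length(sc_sorted)], TRUE)]
  prec_b <- cum_tp[block_end] / block_end
  rec_b <- cum_tp[block_end] / P
  aupr <- sum(diff(c(0, rec_b)) * prec_b)
  # Precision at k (stable top-k; ties broken by position).
  k_values <- sort(unique(as.integer(k_values)))
  k_values <- k_values[k_values >= 1 & k_values <= length(scores)]
  prec_at <- function(k) cum_tp[k] / k
  precision_at_k <- stats::setNames(vapply(k_values, prec_at, numeric(1)),
                                    as.character(k_values))
  early_precision <- prec_at(P)
  prefix_prec <- cum_tp / idx
  ok <- which(prefix_prec >= 1 - alpha)
  fdr_size <- if (length(ok)) max(ok) else 0L
  pred <- as.integer(scores >= threshold)
  confusion <- c(TP = sum(pred == 1L & labels == 1L),
                 FP = sum(pred == 1L & labels == 0L),
                 TN = sum(pred == 0L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L))
  structure(list(auroc = auroc, aupr = aupr,
                 precision_at_k = precision_at_k,
                 early_precision = early_precision,
                 fdr_subnetwork_size = as.integer(fdr_size),
                 confusion = confusion,
                 alpha = alpha, threshold = threshold,
                 n = length(scores)),
            class = "lagnet_eval")
}

#' @export
print.lagnet_eval <- function(x, ...) {
  cat(sprintf("<lagnet_eval> n=%d  AUROC=%.4f  AUPR=%.4f  EP=%.4f  FDR|%.2f size=%d\n",
              x$n, x$auroc, x$aupr, x$early_precision, x$alpha,
              x$fdr_subnetwork_size))
  invisible(x)
}
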