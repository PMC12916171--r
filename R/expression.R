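#' Construct a pseudotime-ordered expression matrix
#'
#' The central data container of the package: a numeric genes-by-cells matrix
#' of normalized expression values with unique gene and cell identifiers and,
#' optionally, a per-cell pseudotime.  When a pseudotime is supplied the cells
#' are reordered (stable sort) so that pseudotime is nondecreasing, since all
#' downstream sliding-window machinery assumes the column order follows the
#' trajectory.
#'
#' @param values Numeric matrix, genes as rows and cells as columns, with
#'   row and column names (gene and cell identifiers).
#' @param pseudotime Optional numeric vector of per-cell pseudotime values,
#'   either named by cell identifier or in current column order.
#' @return An object of class `lagnet_expr` with elements `values` (the
#'   matrix, columns ordered by pseudotime when given) and `pseudotime`
#'   (numeric or `NULL`).
#' @export
expression_matrix <- function(values, pseudotime = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and cell ids as colnames")
  }
  dup <- duplicated(rownames(values))
  if (any(dup)) {
    stop("duplicate gene ids: ", paste(unique(rownames(values)[dup]), collapse = ", "))
  }
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (!is.null(pseudotime)) {
    if (!is.numeric(pseudotime) || length(pseudotime) != ncol(values)) {
      stop("`pseudotime` must be numeric with one value per cell")
    }
    if (!is.null(names(pseudotime))) {
      missing_cells <- setdiff(colnames(values), names(pseudotime))
      extra <- setdiff(names(pseudotime), colnames(values))
      if (length(missing_cells) || length(extra)) {
        stop("pseudotime cell ids do not match expression cell ids (",
             length(missing_cells), " missing, ", length(extra), " extra)")
      }
      pseudotime <- pseudotime[colnames(values)]
    } else {
      names(pseudotime) <- colnames(values)
    }
    if (anyNA(pseudotime)) stop("pseudotime contains missing values")
    ord <- order(pseudotime)  # stable: ties keep input order
    values <- values[, ord, drop = FALSE]
    pseudotime <- pseudotime[ord]
  }
  structure(list(values = values, pseudotime = pseudotime),
            class = "lagnet_expr")
}

#' @export
print.lagnet_expr <- function(x, ...) {
  cat(sprintf("<lagnet_expr> %d genes x %d cells%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$pseudotime)) "" else ", pseudotime-ordered"))
  invisible(x)
}

#' @export
dim.lagnet_expr <- function(x) dim(x$values)

#' Gene and cell identifiers of an expression matrix
#' @param expr A `lagnet_expr` object.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(expr) colnames(expr$values)

#' Load an expression matrix from disk
#'
#' Reads either a dense TSV/CSV (genes as rows, header row of cell ids, first
#' column of gene ids) or a MatrixMarket `.mtx` file accompanied by
#' `genes.txt` / `cells.txt` sidecar files in the same directory.  An optional
#' two-column pseudotime table (cell id, pseudotime) reorders the cells along
#' the trajectory.  A short quality-control summary (dimensions, zero
#' fraction) can be logged.
#'
#' @param path Path to the expression file (`.tsv`, `.csv`, `.txt` or `.mtx`).
#' @param pseudotime_path Optional path to a two-column TSV (cell id,
#'   pseudotime), with or without a header line.
#' @param verbose Log a QC summary via [message()]?
#' @return A [expression_matrix()] object.
#' @export
load_expression <- function(path, pseudotime_path = NULL, verbose = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.txt")
    cf <- file.path(dir, "cells.txt")
    if (!file.exists(gf) || !file.exists(cf)) {
      stop("MTX input requires 'genes.txt' and 'cells.txt' sidecars in ", dir)
    }
    genes <- readLines(gf)
    cells <- readLines(cf)
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("sidecar lengths (", length(genes), " genes, ", length(cells),
           " cells) do not match matrix dimensions ", nrow(m), "x", ncol(m))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, row.names = NULL,
                             colClasses = "character",
                             quote = "\"", comment.char = "")
    if (ncol(raw) < 2) stop("malformed expression table: fewer than 2 columns")
    genes <- raw[[1]]
    body <- raw[, -1, drop = FALSE]
    num <- suppressWarnings(
      vapply(body, function(col) as.numeric(col), numeric(nrow(body)))
    )
    if (nrow(body) == 1) num <- matrix(num, nrow = 1)
    bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- bad[1, 1]; j <- bad[1, 2]
      stop(sprintf(
        "non-numeric value '%s' at line %d (gene '%s'), column %d (cell '%s')",
        body[i, j], i + 1L, genes[i], j + 1L, colnames(body)[j]))
    }
    if (anyNA(num)) {
      i <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at line %d, column %d", i[1] + 1L, i[2] + 1L))
    }
    m <- num
    dimnames(m) <- list(genes, colnames(body))
  }
  pt <- NULL
  if (!is.null(pseudotime_path)) {
    pt <- read_pseudotime(pseudotime_path)
  }
  expr <- expression_matrix(m, pseudotime = pt)
  vlog(verbose, sprintf(
    "loaded %d genes x %d cells; zero fraction %.3f%s",
    nrow(m), ncol(m), mean(m == 0),
    if (is.null(pt)) "" else "; cells reordered by pseudotime"))
  expr
}

read_pseudotime <- function(path) {
  if (!file.exists(path)) stop("pseudotime file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 2) stop("pseudotime table must have two columns (cell, time)")
  # tolerate a header line
  first <- suppressWarnings(as.numeric(tab[1, 2]))
  if (is.na(first)) tab <- tab[-1, , drop = FALSE]
  pt <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(pt)) {
    stop("non-numeric pseudotime at line ", which(is.na(pt))[1])
  }
  stats::setNames(pt, tab[[1]])
}

#' Remove sparsely expressed genes
#'
#' Drops every gene expressed (value strictly greater than zero) in at most
#' `floor(T/10)` of the `T` cells.  This denoising step suppresses genes whose
#' sparse detection carries little trajectory signal.
#'
#' @param expr A [expression_matrix()] object with at least 10 cells.
#' @param verbose Log the number of removed genes?
#' @return The filtered `lagnet_expr`, gene order preserved.
#' @export
filter_low_expression <- function(expr, verbose = FALSE) {
  stopifnot(inherits(expr, "lagnet_expr"))
  n_cells <- ncol(expr$values)
  if (n_cells < 10) stop("need at least 10 cells to apply the 10% rule")
  thr <- floor(n_cells / 10)
  nonzero <- rowSums(expr$values > 0)
  keep <- nonzero > thr
  if (!any(keep)) {
    stop("all genes fall at or below the expression threshold (", thr,
         " cells); review the threshold or the input normalization")
  }
  vlog(verbose, sprintf("removed %d / %d genes expressed in <= %d cells",
                        sum(!keep), length(keep), thr))
  expression_matrix(expr$values[keep, , drop = FALSE],
                    pseudotime = expr$pseudotime)
}

#' Select highly variable genes
#'
#' Keeps the `top_n` genes ranked by per-gene variance across cells.  Ties at
#' the cutoff are broken stably by original gene order.  Variance is computed
#' on the values as loaded; set `log1p = TRUE` to rank on `log1p`-transformed
#' values instead (the selection changes, the returned values do not).
#'
#' @param expr A [expression_matrix()] object.
#' @param top_n Number of genes to keep (positive, at most the gene count).
#' @param log1p Rank genes on `log1p(values)` variance?
#' @return The reduced `lagnet_expr`, selected genes in original order.
#' @export
select_hvg <- function(expr, top_n, log1p = FALSE) {
  stopifnot(inherits(expr, "lagnet_expr"))
  if (!is_count(top_n)) stop("`top_n` must be a positive integer")
  n_genes <- nrow(expr$values)
  if (top_n > n_genes) {
    stop("`top_n` (", top_n, ") exceeds the number of genes (", n_genes, ")")
  }
  v <- if (log1p) {
    matrixStats_rowVars(base::log1p(expr$values))
  } else {
    matrixStats_rowVars(expr$values)
  }
  ord <- order(-v)  # stable: equal variances keep input order
  sel <- sort(ord[seq_len(top_n)])
  expression_matrix(expr$values[sel, , drop = FALSE],
                    pseudotime = expr$pseudotime)
}

# Row variances without looping per gene (denominator n - 1, as stats::var).
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m * m) - n * mu * mu) / (n - 1)
}

#' Write an expression matrix to a dense TSV
#'
#' Companion writer to [load_expression()]: genes as rows, a leading `gene`
#' column, header row of cell ids.  Values are written with full precision so
#' a load round-trip reproduces the matrix.
#'
#' @param expr A [expression_matrix()] object.
#' @param path Output TSV path.
#' @param pseudotime_path Optional path for the two-column pseudotime table.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, pseudotime_path = NULL) {
  stopifnot(inherits(expr, "lagnet_expr"))
  df <- data.frame(gene = rownames(expr$values),
                   format(expr$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pseudotime_path)) {
    if (is.null(expr$pseudotime)) stop("expression object has no pseudotime")
    utils::write.table(
      data.frame(cell = names(expr$pseudotime), pseudotime = expr$pseudotime),
      pseudotime_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
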