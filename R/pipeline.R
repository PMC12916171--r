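#' End-to-end run configuration
#'
#' One declarative object collecting every stage's parameters: preprocessing
#' (highly-variable gene count, seed), aggregation, window geometry (or
#' `NULL` for the automatic grid), enhancement, model, and evaluation.  The
#' two ablation flags reproduce the four classical configurations: with both
#' set, only the sliding window is used ("baseline"); enabling one or the
#' other adds mean aggregation or correlation enhancement; the default
#' ("combined") uses all three.
#'
#' @param top_n Number of highly variable genes to keep (capped at the gene
#'   count at run time).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param aggregation An [aggregation_config()].
#' @param window A [window_config()], or `NULL` to solve one from the
#'   trajectory length via [default_window_config()].
#' @param window_grid `c(p, q)` used when `window` is `NULL`.
#' @param window_steps `c(m, n)` used when `window` is `NULL`.
#' @param combine,ddof Enhancement options, see [enhance()].
#' @param model A [model_config()].
#' @param k_values,alpha Evaluation options, see [compute_metrics()].
#' @param skip_aggregation,skip_enhancement Ablation flags.
#' @return A list of class `lagnet_run_config`.
#' @export
run_config <- function(top_n = 1000, seed = 1,
                       aggregation = aggregation_config(),
                       window = NULL, window_grid = c(64, 64),
                       window_steps = c(5, 5),
                       combine = "euclidean", ddof = 0,
                       model = model_config(),
                       k_values = c(10L, 25L, 50L, 100L), alpha = 0.05,
                       skip_aggregation = FALSE, skip_enhancement = FALSE) {
  structure(list(top_n = top_n, seed = as.integer(seed),
                 aggregation = aggregation, window = window,
                 window_grid = as.integer(window_grid),
                 window_steps = as.integer(window_steps),
                 combine = combine, ddof = ddof, model = model,
                 k_values = k_values, alpha = alpha,
                 skip_aggregation = isTRUE(skip_aggregation),
                 skip_enhancement = isTRUE(skip_enhancement)),
            class = "lagnet_run_config")
}

#' Run the full inference pipeline
#'
#' Executes every stage in order: low-expression filtering, highly-variable
#' gene selection, gold-standard filtering, balanced pair sampling,
#' (optional) neighbor aggregation, per-pair delay-matrix featurization with
#' (optional) enhancement, stratified 3:1:1 split, classifier training with
#' early stopping, test-set scoring, metric computation, and network export
#' over all scored candidate pairs.  Every stage draws its seed from the
#' master seed, so a rerun with an identical configuration reproduces the
#' report exactly.
#'
#' @param expr A [expression_matrix()] object (cells ordered along the
#'   trajectory, or carrying a pseudotime).
#' @param gold A [reference_network()] gold standard.
#' @param config A [run_config()].
#' @param workdir Optional directory; when given, the resolved
#'   configuration, sample table, metrics report, exported network and model
#'   checkpoint are written there.
#' @param refs Optional list of [reference_network()] objects used only to
#'   categorize exported edges.
#' @param verbose Log stage progress?
#' @return A list with `report` (a `lagnet_eval`), `model`, `splits`,
#'   `scores` (all scored pairs), `grn` (exported edge table), `window`,
#'   and `config`.
#' @export
run_pipeline <- function(expr, gold, config = run_config(), workdir = NULL,
                         refs = list(), verbose = FALSE) {
  stopifnot(inherits(expr, "lagnet_expr"), inherits(gold, "lagnet_network"),
            inherits(config, "lagnet_run_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # -- preprocessing (steps 2..5) --
  expr_f <- stage("filter_low_expression",
                  filter_low_expression(expr, verbose = verbose))
  top_n <- min(config$top_n, nrow(expr_f$values))
  expr_f <- stage("select_hvg", select_hvg(expr_f, top_n))
  gold_f <- stage("filter_gold_standard",
                  filter_gold_standard(gold, expr_f, verbose = verbose))
  pairs <- stage("build_pair_samples",
                 build_pair_samples(gold_f, expr_f,
                                    seed = derive_seed(config$seed, 1)))
  # -- aggregation --
  expr_a <- if (config$skip_aggregation) {
    expr_f
  } else {
    stage("aggregate_expression",
          aggregate_expression(expr_f, config$aggregation))
  }
  # -- window geometry --
  T_len <- ncol(expr_a$values)
  window <- config$window %||%
    stage("default_window_config",
          default_window_config(T_len, p = config$window_grid[1],
                                q = config$window_grid[2],
                                m = config$window_steps[1],
                                n = config$window_steps[2],
                                verbose = verbose))
  vlog(verbose, sprintf("window: p=%d q=%d m=%d n=%d w=%d",
                        window$p, window$q, window$m, window$n, window$w))
  # -- featurization --
  feats <- stage("featurize_pairs",
                 featurize_pairs(pairs, expr_a, window,
                                 enhanced = !config$skip_enhancement,
                                 combine = config$combine, ddof = config$ddof))
  # -- split --
  splits <- stage("split_samples",
                  split_samples(pairs, seed = derive_seed(config$seed, 2)))
  key <- paste(pairs$tf, pairs$target)
  pick <- function(s) feats[match(paste(s$tf, s$target), key)]
  # -- model --
  mcfg <- config$model
  mcfg$seed <- derive_seed(config$seed, 3)
  model <- stage("build_model", build_model(mcfg, c(window$p, window$q)))
  model <- stage("train", train_model(model,
                                      pick(splits$train), splits$train$label,
                                      pick(splits$val), splits$val$label,
                                      verbose = verbose))
  # -- evaluation on held-out pairs --
  test_scores <- stage("predict", predict(model, pick(splits$test)))
  report <- stage("compute_metrics",
                  compute_metrics(test_scores, splits$test$label,
                                  k_values = config$k_values,
                                  alpha = config$alpha))
  # -- ranked export over all candidate pairs --
  all_scores <- data.frame(tf = pairs$tf, target = pairs$target,
                           score = stage("predict", predict(model, feats)),
                           label = pairs$label, stringsAsFactors = FALSE)
  grn <- stage("export_grn", export_grn(all_scores, gold_f, refs = refs))
  out <- list(report = report, model = model, splits = splits,
              scores = all_scores, grn = grn, window = window,
              config = config)
  if (!is.null(workdir)) {
    if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
    jsonlite::write_json(resolve_config(config, window),
                         file.path(workdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(all_scores, file.path(workdir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(grn, file.path(workdir, "grn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auroc = report$auroc, aupr = report$aupr,
           precision_at_k = as.list(report$precision_at_k),
           early_precision = report$early_precision,
           fdr_subnetwork_size = report$fdr_subnetwork_size,
           confusion = as.list(report$confusion),
           n_test = report$n, best_epoch = model$best_epoch),
      file.path(workdir, "report.json"), auto_unbox = TRUE, digits = NA)
    saveRDS(model, file.path(workdir, "model.rds"))
    vlog(verbose, "artifacts written to ", workdir)
  }
  out
}

# Flatten the configuration (plus the solved window) for the run log.
resolve_config <- function(config, window) {
  list(seed = config$seed, top_n = config$top_n,
       skip_aggregation = config$skip_aggregation,
       skip_enhancement = config$skip_enhancement,
       aggregation = unclass(config$aggregation),
       window = unclass(window),
       combine = config$combine, ddof = config$ddof,
       model = unclass(config$model),
       k_values = config$k_values, alpha = config$alpha,
       package_version = as.character(utils::packageVersion("lagnet")))
}
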