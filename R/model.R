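#' Configuration of the hybrid recurrent-convolutional pair classifier
#'
#' The classifier reads each (enhanced) p x q delay matrix as a length-p
#' sequence of q-dimensional steps -- rows (TF windows, the forward
#' pseudotime axis) are the recurrent time steps, columns (delays) the
#' per-step features.  A bidirectional GRU with `gru_units` units per
#' direction returns the full sequence, which is treated as a single-channel
#' 2-D map and passed through a stack of valid 3x3 convolutions with ReLU,
#' one max-pool, dropout, and three dense layers (512, 128, 1) ending in a
#' sigmoid.  Training minimizes binary cross-entropy with SGD (momentum,
#' exponentially decaying learning rate) and early-stops on the best
#' validation AUPR.
#'
#' Ablation variants are expressed through `rnn_type` (`"none"` gives the
#' CNN-only model, `"rnn"`/`"gru"`/`"lstm"` the unidirectional backbones,
#' `"bigru"` the default) and through `conv_filters` (empty for the
#' recurrent-only model, or deeper stacks such as `c(64, 32, 64)`).
#'
#' @param gru_units Recurrent units per direction (default 128).
#' @param conv_filters Integer vector of filters per conv layer (0 to 4
#'   layers; default `c(64, 32)`).
#' @param kernel_size Square convolution kernel (default 3).
#' @param pool_size Max-pool size applied once after the conv stack.
#' @param dropout_rates Two rates in `[0, 1)`: after the feature extractor
#'   and before the output unit (default `c(0.25, 0.5)`).
#' @param dense_sizes Three dense layer sizes; the last must be 1
#'   (default `c(512, 128, 1)`).
#' @param rnn_type One of `"bigru"`, `"gru"`, `"lstm"`, `"rnn"`, `"none"`.
#' @param learning_rate,lr_decay,momentum SGD hyperparameters: initial rate,
#'   per-epoch exponential decay factor, and classical momentum.
#' @param batch_size,epochs,patience Mini-batch size, maximum epochs, and
#'   early-stopping patience (epochs without validation-AUPR improvement).
#' @param rows_as_steps If `FALSE`, matrices are transposed before entering
#'   the network (delays become the time steps).
#' @param seed Integer seed governing initialization, batch shuffling and
#'   dropout.
#' @return A list of class `lagnet_model_config`.
#' @export
model_config <- function(gru_units = 128, conv_filters = c(64, 32),
                         kernel_size = 3, pool_size = 2,
                         dropout_rates = c(0.25, 0.5),
                         dense_sizes = c(512, 128, 1),
                         rnn_type = c("bigru", "gru", "lstm", "rnn", "none"),
                         learning_rate = 0.01, lr_decay = 0.95,
                         momentum = 0.9, batch_size = 32, epochs = 50,
                         patience = 10, rows_as_steps = TRUE, seed = 1) {
  rnn_type <- match.arg(rnn_type)
  if (length(conv_filters) > 4) stop("at most 4 convolutional layers")
  if (length(conv_filters) && !all(vapply(conv_filters, is_count, TRUE))) {
    stop("`conv_filters` must be positive integers")
  }
  if (length(dense_sizes) != 3 || dense_sizes[3] != 1) {
    stop("`dense_sizes` must have three entries ending in 1")
  }
  if (length(dropout_rates) != 2 ||
      any(dropout_rates < 0 | dropout_rates >= 1)) {
    stop("`dropout_rates` must be two rates in [0, 1)")
  }
  if (rnn_type != "none" && !is_count(gru_units)) {
    stop("`gru_units` must be a positive integer")
  }
  structure(list(gru_units = as.integer(gru_units),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dropout_rates = as.numeric(dropout_rates),
                 dense_sizes = as.integer(dense_sizes),
                 rnn_type = rnn_type,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 rows_as_steps = isTRUE(rows_as_steps),
                 seed = as.integer(seed)),
            class = "lagnet_model_config")
}

# Internal: configuration list consumed by the C++ core, with the
# orientation already resolved (p = time steps, q = per-step features).
cpp_config <- function(cfg, input_shape) {
  shape <- if (cfg$rows_as_steps) input_shape else rev(input_shape)
  rnn_code <- switch(cfg$rnn_type,
                     none = 0L, rnn = 1L, gru = 2L, lstm = 3L, bigru = 2L)
  list(p = as.integer(shape[1]), q = as.integer(shape[2]),
       rnn_type = rnn_code, bidir = cfg$rnn_type == "bigru",
       h = cfg$gru_units, conv = as.integer(cfg$conv_filters),
       kernel = cfg$kernel_size, pool = cfg$pool_size,
       d1 = cfg$dense_sizes[1], d2 = cfg$dense_sizes[2],
       drop1 = cfg$dropout_rates[1], drop2 = cfg$dropout_rates[2])
}

#' Build (initialize) a pair classifier
#'
#' Allocates and initializes the network parameters for a given input shape.
#' Weights use Glorot-uniform initialization, biases start at zero (the LSTM
#' forget-gate bias at one), all drawn deterministically from the
#' configuration seed: two builds with the same seed are identical.
#'
#' @param cfg A [model_config()].
#' @param input_shape Integer vector `c(p, q)`: the delay-matrix shape.
#' @return An object of class `lagnet_model` with elements `config`,
#'   `input_shape`, `theta` (flat parameter vector), `layout`, `trained`,
#'   `history`.
#' @export
build_model <- function(cfg, input_shape) {
  stopifnot(inherits(cfg, "lagnet_model_config"),
            length(input_shape) == 2, all(input_shape >= 1))
  input_shape <- as.integer(input_shape)
  if (length(cfg$conv_filters) > 0 && any(input_shape < 4)) {
    stop("input shape ", paste(input_shape, collapse = "x"),
         " too small for convolutional layers (need p, q >= 4)")
  }
  cc <- cpp_config(cfg, input_shape)
  lay <- nn_layout(cc)  # errors name the collapsing layer, if any
  theta <- numeric(lay$total)
  with_seed(cfg$seed, {
    for (i in seq_along(lay$name)) {
      nm <- lay$name[i]
      nr <- lay$nrow[i]; nc <- lay$ncol[i]
      span <- lay$offset[i]:(lay$offset[i] + nr * nc - 1)
      if (grepl("_b$", nm)) {
        theta[span] <- 0
        if (cfg$rnn_type == "lstm" && grepl("^rnn", nm)) {
          h <- cfg$gru_units  # forget gate is the second block of 4
          theta[span][(h + 1):(2 * h)] <- 1
        }
      } else {
        lim <- sqrt(6 / (nr + nc))
        theta[span] <- stats::runif(nr * nc, -lim, lim)
      }
    }
  })
  structure(list(config = cfg, input_shape = input_shape, theta = theta,
                 layout = lay, trained = FALSE, history = NULL,
                 best_epoch = NA_integer_),
            class = "lagnet_model")
}

#' @export
print.lagnet_model <- function(x, ...) {
  cat(sprintf(
    "<lagnet_model> %s + CNN[%s], input %dx%d, %s parameters, %s\n",
    toupper(x$config$rnn_type),
    paste(x$config$conv_filters, collapse = "-"),
    x$input_shape[1], x$input_shape[2],
    format(length(x$theta), big.mark = ","),
    if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
    else "untrained"))
  invisible(x)
}

# Internal: stack a list of matrices / lagnet objects into a p x q x B array
# in the orientation the network expects.
as_input_array <- function(x, model) {
  mats <- lapply(x, function(m) {
    if (inherits(m, "lagnet_enhanced") || inherits(m, "lagnet_delay")) {
      m <- m$values
    }
    if (!is.matrix(m)) stop("inputs must be matrices or lagnet matrix objects")
    if (!all(dim(m) == model$input_shape)) {
      stop("input of shape ", paste(dim(m), collapse = "x"),
           " does not match the model's expected shape ",
           paste(model$input_shape, collapse = "x"))
    }
    if (model$config$rows_as_steps) m else t(m)
  })
  array(unlist(mats, use.names = FALSE),
        dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
}

#' Train the pair classifier
#'
#' Minimizes binary cross-entropy with mini-batch SGD (classical momentum,
#' exponentially decaying learning rate).  After each epoch the model is
#' scored on the validation pairs; the parameters of the epoch with the best
#' validation AUPR are kept, and training stops early after
#' `config$patience` epochs without improvement.  The run is a deterministic
#' function of the data and the configuration seed.
#'
#' @param model An untrained (or trained) [build_model()] object.
#' @param x_train,x_val Lists of enhanced/delay matrices (or plain matrices)
#'   matching the model's input shape.
#' @param y_train,y_val Binary labels.
#' @param verbose Log per-epoch loss and validation metrics?
#' @return The model with `theta` set to the best parameters, `trained =
#'   TRUE`, and a `history` data frame (epoch, loss, val_auroc, val_aupr).
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        verbose = FALSE) {
  stopifnot(inherits(model, "lagnet_model"))
  cfg <- model$config
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (length(unique(y_train)) < 2) stop("training set has a single class")
  if (length(unique(y_val)) < 2) stop("validation set has a single class")
  Xtr <- as_input_array(x_train, model)
  Xva <- as_input_array(x_val, model)
  cc <- cpp_config(cfg, model$input_shape)
  theta <- model$theta + 0  # explicit copy: the SGD step updates in place
  vel <- numeric(length(theta))
  n <- length(y_train)
  best <- list(aupr = -Inf, theta = theta, epoch = 0L)
  hist <- vector("list", cfg$epochs)
  stale <- 0L
  with_seed(derive_seed(cfg$seed, 101), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate * cfg$lr_decay^(epoch - 1)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        res <- nn_batch(theta, cc, Xtr[, , idx, drop = FALSE],
                        y_train[idx], TRUE)
        if (!is.finite(res$loss)) {
          stop("training loss diverged (NaN/Inf) at epoch ", epoch,
               "; try a lower learning rate")
        }
        nn_sgd_step(theta, vel, res$grad, lr, cfg$momentum)
        losses <- c(losses, res$loss)
      }
      val <- nn_batch(theta, cc, Xva, numeric(0), FALSE)
      vm <- compute_metrics(val$scores, y_val)
      hist[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                  val_auroc = vm$auroc, val_aupr = vm$aupr)
      vlog(verbose, sprintf("epoch %3d  loss %.4f  val AUROC %.3f AUPR %.3f",
                            epoch, mean(losses), vm$auroc, vm$aupr))
      if (vm$aupr > best$aupr) {
        best <- list(aupr = vm$aupr, theta = theta + 0, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
  })
  model$theta <- best$theta
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model
}

#' Predict interaction scores
#'
#' Applies the trained classifier to a list of matrices, returning one score
#' in `[0, 1]` per pair.  The forward pass has no cross-sample interaction,
#' so scores are order-preserving and batch-size independent.
#'
#' @param object A trained `lagnet_model`.
#' @param newdata A list of enhanced/delay matrices (or plain matrices)
#'   matching the training input shape.
#' @param ... Unused.
#' @return Numeric vector of scores, one per element of `newdata`.
#' @export
predict.lagnet_model <- function(object, newdata, ...) {
  X <- as_input_array(newdata, object)
  cc <- cpp_config(object$config, object$input_shape)
  res <- nn_batch(object$theta, cc, X, numeric(0), FALSE)
  as.numeric(res$scores)
}
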