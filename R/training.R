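#' Mean cross-entropy of predicted probabilities
#'
#' `-mean(log p_true)` over the batch, with predicted probabilities
#' clamped below at 1e-12 so a zero probability on the true class gives
#' a large finite loss rather than infinity.
#'
#' @param pred `n x K` matrix of class probabilities (rows sum to 1).
#' @param truth Integer labels, 0-based, length `n`.
#' @return A non-negative scalar.
#' @export
#' @examples
#' cross_entropy(matrix(rep(0.2, 5), 1), 0)  # log(5)
cross_entropy <- function(pred, truth) {
  stopifnot(is.matrix(pred), nrow(pred) == length(truth),
            all(truth >= 0), all(truth < ncol(pred)))
  p <- pred[cbind(seq_len(nrow(pred)), truth + 1L)]
  p <- pmax(p, 1e-12)
  -mean(log(p))
}

#' Full-training configuration
#'
#' @param batch_size Minibatch size (default 256).
#' @param epochs Training epochs (default 500).
#' @param validation_fraction Fraction of the training portion carved
#'   out (stratified) as the validation set (default 0.1).
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @param standardize Standardize inputs by the global training mean and
#'   standard deviation (one scalar pair, stored with the model).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256L, epochs = 500L,
                         validation_fraction = 0.1, seed = 1L,
                         standardize = TRUE) {
  stopifnot(batch_size >= 1, epochs >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 standardize = isTRUE(standardize)),
            class = "train_config")
}

#' Short-budget fitness-evaluation configuration for the optimizer loop
#'
#' Candidate hyperparameter vectors are scored by a deliberately short
#' training run (default 10 epochs, far below the final training
#' budget) whose final validation cross-entropy is the optimizer's
#' objective.  Scores are cached keyed on the decoded hyperparameters,
#' so rounding-equivalent optimizer positions never retrain.
#'
#' @param search_epochs Epochs per fitness evaluation (default 10).
#' @param batch_size Minibatch size during search (default 32; small
#'   batches give more updates per short epoch).
#' @param max_train_rows Optional cap on training rows used per
#'   evaluation (stratified subsample; `Inf` disables).
#' @param cache Reuse scores for previously seen decoded vectors.
#' @return A `fitness_config` list.
#' @export
fitness_config <- function(search_epochs = 10L, batch_size = 32L,
                           max_train_rows = Inf, cache = TRUE) {
  stopifnot(search_epochs >= 1, batch_size >= 1)
  structure(list(search_epochs = as.integer(search_epochs),
                 batch_size = as.integer(batch_size),
                 max_train_rows = max_train_rows,
                 cache = isTRUE(cache)),
            class = "fitness_config")
}

# Stratified row subsample keeping per-class proportions
stratified_cap <- function(y, max_rows, seed) {
  n <- length(y)
  if (!is.finite(max_rows) || n <= max_rows) return(seq_len(n))
  frac <- max_rows / n
  keep <- integer(0)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      keep <- c(keep, sample(idx, max(2L, round(frac * length(idx)))))
    }
  })
  sort(keep)
}

standardize_params <- function(X, enabled) {
  if (!enabled) return(list(center = 0, scale = 1))
  s <- sd(X)
  list(center = mean(X), scale = if (s > 0) s else 1)
}

#' Train a model with best-validation checkpointing
#'
#' Minimizes the cross-entropy by minibatch Adam at the spec's learning
#' rate.  After every epoch the validation accuracy is compared with
#' the incumbent best and the better snapshot is retained; the model
#' returned is the best-validation checkpoint, not the last epoch.  If
#' `data` has no `val` element, a stratified validation set of
#' `validation_fraction` is carved out of the training rows.
#'
#' @param spec A `model_spec`.
#' @param data A list with `train` (and optionally `val`)
#'   `windowed_dataset`s, or a single `windowed_dataset` to be split.
#' @param cfg A [train_config()].
#' @return A list: `model` (trained `cnn_model` at the best-validation
#'   checkpoint), `history` (per-epoch data frame: `epoch`,
#'   `train_loss`, `val_loss`, `val_acc`), `best_epoch`,
#'   `best_val_acc`, `diverged`.
#' @export
train_model <- function(spec, data, cfg = train_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "train_config"))
  if (inherits(data, "windowed_dataset")) data <- list(train = data)
  if (is.null(data$val)) {
    sp <- split_dataset(data$train, 1 - cfg$validation_fraction,
                        seed = derive_seed(cfg$seed, "val-carve"))
    data <- list(train = sp$train, val = sp$test)
  }
  std <- standardize_params(data$train$X, cfg$standardize)
  Xtr <- (data$train$X - std$center) / std$scale
  Xva <- (data$val$X - std$center) / std$scale
  model <- instantiate(spec, seed = derive_seed(cfg$seed, "weights"))
  fit <- .cnn_train(spec$layers, model$weights, Xtr,
                    as.integer(data$train$y), Xva, as.integer(data$val$y),
                    cfg$epochs, min(cfg$batch_size, nrow(Xtr)),
                    spec$learning_rate, derive_seed(cfg$seed, "sgd"))
  model$weights <- fit$best_weights
  model$center <- std$center
  model$scale <- std$scale
  list(model = model, history = fit$history,
       best_epoch = fit$best_epoch, best_val_acc = fit$best_val_acc,
       diverged = fit$diverged)
}

# package-local fitness cache
.fitness_cache <- new.env(parent = emptyenv())

fitness_key <- function(hp, fit_cfg, seed, n_train) {
  paste(hp$n_kernels, hp$kernel_size, hp$activation,
        signif(hp$dropout, 10), signif(hp$learning_rate, 10), hp$pool_size,
        fit_cfg$search_epochs, fit_cfg$batch_size, seed, n_train,
        sep = "|")
}

#' Clear the fitness-evaluation cache
#' @export
clear_fitness_cache <- function() {
  rm(list = ls(.fitness_cache), envir = .fitness_cache)
  invisible(NULL)
}

#' Objective value of a hyperparameter vector
#'
#' Builds the network for `hp`, trains it for the short search budget,
#' and returns the final validation cross-entropy (lower is better).
#' An unbuildable architecture (e.g. the pooling window collapses the
#' sequence) or a diverged run scores `+Inf`, which the optimizer
#' treats as a discarded candidate.  Identical `(hp, data, seed)`
#' triples return identical values, via determinism and the cache.
#'
#' @param hp An `hp_vector`.
#' @param data A list with `train` and `val` `windowed_dataset`s.
#' @param fit_cfg A [fitness_config()].
#' @param seed Integer seed.
#' @param n_classes Number of classes (defaults to the number of
#'   distinct training labels).
#' @param n_blocks Number of convolution blocks (default 6).
#' @return The validation cross-entropy after `search_epochs` epochs.
#' @export
evaluate_fitness <- function(hp, data, fit_cfg = fitness_config(),
                             seed = 1L, n_classes = NULL, n_blocks = 6L) {
  stopifnot(inherits(hp, "hp_vector"), inherits(fit_cfg, "fitness_config"),
            !is.null(data$train), !is.null(data$val))
  if (is.null(n_classes)) n_classes <- length(unique(data$train$y))
  keep <- stratified_cap(data$train$y, fit_cfg$max_train_rows,
                         derive_seed(seed, "fitness-cap"))
  key <- fitness_key(hp, fit_cfg, seed, length(keep))
  if (fit_cfg$cache && !is.null(.fitness_cache[[key]])) {
    return(.fitness_cache[[key]])
  }
  spec <- tryCatch(
    build_model_spec(hp, input_len = data$train$chunk_len,
                     n_classes = n_classes, n_blocks = n_blocks),
    error = function(e) NULL)
  if (is.null(spec)) return(Inf)
  train <- ds_take(data$train, keep)
  std <- standardize_params(train$X, TRUE)
  Xtr <- (train$X - std$center) / std$scale
  Xva <- (data$val$X - std$center) / std$scale
  model <- instantiate(spec, seed = derive_seed(seed, "fitness-weights"))
  fit <- .cnn_train(spec$layers, model$weights, Xtr, as.integer(train$y),
                    Xva, as.integer(data$val$y), fit_cfg$search_epochs,
                    min(fit_cfg$batch_size, nrow(Xtr)),
                    spec$learning_rate, derive_seed(seed, "fitness-sgd"))
  value <- if (fit$diverged || nrow(fit$history) == 0) {
    Inf
  } else {
    v <- fit$history$val_loss[nrow(fit$history)]
    if (!is.finite(v)) Inf else v
  }
  if (fit_cfg$cache) .fitness_cache[[key]] <- value
  value
}

#' Loss curves across a set of minibatch sizes
#'
#' Trains one model per batch size from the same initial weights and
#' with the same seed, and collects the per-epoch loss curves, as a
#' harness for studying the batch-size / convergence trade-off.
#'
#' @param spec A `model_spec`.
#' @param data As for [train_model()].
#' @param sizes Batch sizes (default `c(32, 64, 128, 256, 512, 1024)`).
#' @param epochs Epochs per run.
#' @param seed Shared seed.
#' @return A long data frame: `batch_size`, `epoch`, `train_loss`,
#'   `val_loss`, `val_acc`.
#' @export
batch_size_sweep <- function(spec, data,
                             sizes = c(32L, 64L, 128L, 256L, 512L, 1024L),
                             epochs = 20L, seed = 1L) {
  stopifnot(all(sizes >= 1))
  if (inherits(data, "windowed_dataset")) data <- list(train = data)
  n_train <- nrow(data$train$X)
  if (any(sizes > n_train)) {
    stop(sprintf("batch size exceeds the %d training rows", n_train),
         call. = FALSE)
  }
  curves <- lapply(sizes, function(bs) {
    cfg <- train_config(batch_size = bs, epochs = epochs, seed = seed)
    fit <- train_model(spec, data, cfg)
    cbind(batch_size = bs, fit$history)
  })
  do.call(rbind, curves)
}
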