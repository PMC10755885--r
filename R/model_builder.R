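#' Build the block-structured 1D-CNN specification
#'
#' The network consists of `n_blocks` repetitions of
#' `[conv, batch_norm, dropout, max_pool]` followed by `[flatten,
#' dense]`, for `4 * n_blocks + 2` layers in total (26 at the default
#' six blocks).  Per-block convolution filter counts follow the
#' schedule `delta, delta-10, delta-15, delta-20, delta-25, delta-30,
#' ...` (the decrement is 10 after the first block and 5 thereafter),
#' clamped to at least one filter.  Every convolution uses the same
#' kernel size and activation with length-preserving padding; every
#' dropout uses the same rate; every pooling layer uses the same window
#' with ceiling-length output; the final stage is a flatten and a dense
#' softmax layer with one unit per class.
#'
#' @param hp An [hp_vector()].
#' @param input_len Input sequence length (default 178 samples, one
#'   windowed EEG second).
#' @param n_classes Number of output classes (default 5).
#' @param n_blocks Number of convolution blocks (default 6).
#' @return An object of class `model_spec`: a list of layer specs plus
#'   metadata.
#' @export
#' @examples
#' spec <- build_model_spec(hp_vector(50, 10, 0, 0.2, 1e-3, 2))
#' length(spec$layers)  # 26
build_model_spec <- function(hp, input_len = 178L, n_classes = 5L,
                             n_blocks = 6L) {
  stopifnot(inherits(hp, "hp_vector"), input_len >= 1, n_classes >= 2,
            n_blocks >= 1)
  # the sequence length after b poolings with ceiling division
  len <- input_len
  for (b in seq_len(n_blocks)) len <- ceiling(len / hp$pool_size)
  if (len < 1) {
    stop(sprintf("input length %d cannot survive %d poolings of window %d",
                 input_len, n_blocks, hp$pool_size), call. = FALSE)
  }
  decrements <- cumsum(c(0, 10, rep(5, max(n_blocks - 2, 0))))[seq_len(n_blocks)]
  filters <- pmax(hp$n_kernels - decrements, 1L)
  layers <- list()
  for (b in seq_len(n_blocks)) {
    layers[[length(layers) + 1L]] <- list(kind = "conv",
                                          filters = as.integer(filters[b]),
                                          kernel = hp$kernel_size,
                                          activation = hp$activation)
    layers[[length(layers) + 1L]] <- list(kind = "batch_norm")
    layers[[length(layers) + 1L]] <- list(kind = "dropout",
                                          rate = hp$dropout)
    layers[[length(layers) + 1L]] <- list(kind = "max_pool",
                                          pool = hp$pool_size)
  }
  layers[[length(layers) + 1L]] <- list(kind = "flatten")
  layers[[length(layers) + 1L]] <- list(kind = "dense",
                                        units = as.integer(n_classes))
  structure(list(layers = layers, input_len = as.integer(input_len),
                 n_classes = as.integer(n_classes),
                 n_blocks = as.integer(n_blocks),
                 filters = as.integer(filters),
                 learning_rate = hp$learning_rate,
                 hp = hp),
            class = "model_spec")
}

#' Deterministic layer-by-layer shape inference
#'
#' Fills `input_shape` and `output_shape` for every layer of the spec,
#' as `(length, channels)` pairs (a single integer after flattening).
#' Rules: convolution preserves length and sets channels to its filter
#' count; batch normalization and dropout are identities; max-pooling
#' maps length `L` to `ceiling(L / m)`; flatten multiplies length by
#' channels; dense outputs `n_classes`.
#'
#' @param spec A `model_spec`.
#' @return The spec with a `shapes` data frame attached: one row per
#'   layer with columns `layer`, `kind`, `in_len`, `in_ch`, `out_len`,
#'   `out_ch` (flatten/dense rows use `out_len` for the flat size and
#'   `NA` channels).
#' @export
#' @examples
#' spec <- infer_shapes(build_model_spec(hp_vector()))
#' spec$shapes
infer_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  len <- spec$input_len
  ch <- 1L
  flat <- NA_integer_
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    in_len <- if (is.na(flat)) len else flat
    in_ch <- if (is.na(flat)) ch else NA_integer_
    switch(ly$kind,
      conv = { ch <- ly$filters },
      batch_norm = {},
      dropout = {},
      max_pool = { len <- as.integer(ceiling(len / ly$pool)) },
      flatten = { flat <- len * ch },
      dense = { flat <- ly$units },
      stop(sprintf("unknown layer kind '%s'", ly$kind), call. = FALSE))
    if (len < 1) stop("zero-length intermediate sequence", call. = FALSE)
    rows[[i]] <- data.frame(
      layer = i, kind = ly$kind,
      in_len = in_len, in_ch = in_ch,
      out_len = if (is.na(flat)) len else flat,
      out_ch = if (is.na(flat)) ch else NA_integer_)
  }
  spec$shapes <- do.call(rbind, rows)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("1D-CNN model spec: %d layers (%d blocks), input (%d, 1), %d classes\n",
              length(x$layers), x$n_blocks, x$input_len, x$n_classes))
  cat("  filters:", paste(x$filters, collapse = ", "), "\n")
  hp <- x$hp
  cat(sprintf("  kernel %d, activation %s, dropout %.3g, pool %d, lr %.3g\n",
              hp$kernel_size, activation_name(hp$activation), hp$dropout,
              hp$pool_size, hp$learning_rate))
  if (!is.null(x$shapes)) {
    print(x$shapes, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a model spec as a structured text document
#'
#' @param spec A `model_spec` (shapes are inferred if absent).
#' @param path Output path (tab-separated layer table).
#' @return The path, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$shapes)) spec <- infer_shapes(spec)
  tab <- spec$shapes
  tab$parameter <- vapply(spec$layers, function(ly) {
    switch(ly$kind,
           conv = sprintf("filters=%d kernel=%d activation=%s", ly$filters,
                          ly$kernel, activation_name(ly$activation)),
           dropout = sprintf("rate=%g", ly$rate),
           max_pool = sprintf("pool=%d", ly$pool),
           dense = sprintf("units=%d", ly$units),
           "")
  }, character(1))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Instantiate a trainable model from a spec
#'
#' Allocates seeded (Glorot-uniform) weights for the spec using the
#' package's compiled 1D-CNN engine and returns a handle usable with
#' [predict.cnn_model()], [train_model()] and [model_shapes()].  Two
#' instantiations with the same seed hold identical initial weights.
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_model` with fields `spec`, `weights`
#'   and input-standardization parameters (`center`, `scale`, identity
#'   until trained).
#' @export
instantiate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(spec$shapes)) spec <- infer_shapes(spec)
  weights <- .cnn_init(spec$layers, spec$input_len, as.integer(seed))
  structure(list(spec = spec, weights = weights, seed = as.integer(seed),
                 center = 0, scale = 1),
            class = "cnn_model")
}

#' Predicted class probabilities from a model
#'
#' @param object A `cnn_model`.
#' @param newdata A numeric matrix with one row per sequence of length
#'   `input_len`, or a `windowed_dataset`.
#' @param ... Unused.
#' @return An `n x n_classes` matrix of probabilities; rows sum to 1.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "windowed_dataset")) newdata <- newdata$X
  stopifnot(is.matrix(newdata), ncol(newdata) == object$spec$input_len)
  X <- (newdata - object$center) / object$scale
  .cnn_predict(object$spec$layers, object$weights, X)
}

#' Framework-reported layer shapes from an actual forward pass
#'
#' Runs a dummy sequence through the compiled engine and records the
#' dimensions of every intermediate activation array.  This is the
#' engine's own account of the shapes, independent of [infer_shapes()],
#' and is used to cross-check the native shape arithmetic.
#'
#' @param model A `cnn_model`.
#' @return An integer matrix with columns `length` and `channels`, one
#'   row per layer (`channels` is -1 after flattening).
#' @export
model_shapes <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  .cnn_forward_shapes(model$spec$layers, model$weights,
                      model$spec$input_len)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("1D-CNN model (%d layers, input length %d, %d classes, seed %d)\n",
              length(x$spec$layers), x$spec$input_len, x$spec$n_classes,
              x$seed))
  invisible(x)
}
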