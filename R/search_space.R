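#' The six-dimensional CNN hyperparameter search space
#'
#' Dimension order is fixed: first-block filter count (`n_kernels`),
#' kernel size (`kernel_size`), activation code (`activation`), dropout
#' probability (`dropout`), log10 learning rate (`log10_eta`), and
#' pooling window (`pool_size`).  The learning rate is searched on a
#' logarithmic scale because its admissible range `[1e-5, 1)` spans four
#' decades; the optimizer coordinate is `log10(eta)`.
#'
#' @return A data frame with columns `name`, `kind`, `low`, `high`.
#' @export
#' @examples
#' hp_space()
hp_space <- function() {
  data.frame(
    name = c("n_kernels", "kernel_size", "activation", "dropout",
             "log10_eta", "pool_size"),
    kind = c("integer", "integer", "categorical", "continuous",
             "log-continuous", "integer"),
    low = c(40, 1, 0, 0, -5, 2),
    high = c(100, 20, 2, 0.6, 0, 20),
    stringsAsFactors = FALSE)
}

#' Bounds of the hyperparameter space as an [mfo_config()] bounds list
#' @return A list of six `c(lower, upper)` pairs in space order.
#' @export
hp_bounds <- function() {
  sp <- hp_space()
  lapply(seq_len(nrow(sp)), function(i) c(sp$low[i], sp$high[i]))
}

# eta < 1 strictly: keep the log10 coordinate just below 0
ETA_LOG_MAX <- -1e-9

#' Decode a continuous optimizer position into concrete hyperparameters
#'
#' Coordinates are first clipped to the space bounds.  Integer dimensions
#' (filters, kernel size, pooling window) are rounded half away from
#' zero; the activation coordinate is rounded to a code in `{0, 1, 2}`;
#' dropout passes through; the fifth coordinate is interpreted as
#' `log10(eta)` and exponentiated, with `eta` kept strictly below 1.
#'
#' @param pos Numeric vector of length 6 in space order.
#' @return An object of class `hp_vector` with fields `n_kernels`,
#'   `kernel_size`, `activation`, `dropout`, `learning_rate`,
#'   `pool_size`.
#' @export
#' @examples
#' decode_position(c(50.4, 9.6, 0.3, 0.2, -3, 2.2))
decode_position <- function(pos) {
  if (length(pos) != 6 || !is.numeric(pos)) {
    stop("position must be a numeric vector of length 6", call. = FALSE)
  }
  sp <- hp_space()
  hi <- sp$high
  hi[5] <- ETA_LOG_MAX
  pos <- pmin(pmax(pos, sp$low), hi)
  code <- round_half_away(pos[3])
  hp <- list(
    n_kernels = as.integer(round_half_away(pos[1])),
    kernel_size = as.integer(round_half_away(pos[2])),
    activation = as.integer(min(max(code, 0), 2)),
    dropout = pos[4],
    learning_rate = 10^pos[5],
    pool_size = as.integer(round_half_away(pos[6])))
  # rounding can nudge an integer dimension past its bound (e.g. 99.7 -> 100
  # is fine but 100.0 stays 100); clamp defensively
  hp$n_kernels <- as.integer(min(max(hp$n_kernels, 40L), 100L))
  hp$kernel_size <- as.integer(min(max(hp$kernel_size, 1L), 20L))
  hp$pool_size <- as.integer(min(max(hp$pool_size, 2L), 20L))
  structure(hp, class = "hp_vector")
}

#' Construct a hyperparameter vector directly
#'
#' @param n_kernels First-block convolution filter count, 40..100.
#' @param kernel_size Convolution kernel size, 1..20.
#' @param activation Activation code: 0 = ReLU, 1 = sigmoid, 2 = tanh.
#' @param dropout Dropout probability, 0..0.6.
#' @param learning_rate Adam learning rate, `[1e-5, 1)`.
#' @param pool_size Max-pooling window, 2..20.
#' @return An `hp_vector`.
#' @export
hp_vector <- function(n_kernels = 50L, kernel_size = 10L, activation = 0L,
                      dropout = 0.2, learning_rate = 1e-3, pool_size = 2L) {
  stopifnot(n_kernels >= 40, n_kernels <= 100,
            kernel_size >= 1, kernel_size <= 20,
            activation %in% 0:2,
            dropout >= 0, dropout <= 0.6,
            learning_rate >= 1e-5, learning_rate < 1,
            pool_size >= 2, pool_size <= 20)
  structure(list(n_kernels = as.integer(n_kernels),
                 kernel_size = as.integer(kernel_size),
                 activation = as.integer(activation),
                 dropout = dropout,
                 learning_rate = learning_rate,
                 pool_size = as.integer(pool_size)),
            class = "hp_vector")
}

#' Re-encode a hyperparameter vector as an optimizer position
#'
#' Inverse of [decode_position()] up to the rounding applied there, so
#' `decode_position(encode_hp(hp))` reproduces `hp` exactly.
#'
#' @param hp An `hp_vector`.
#' @return Numeric vector of length 6 in space order.
#' @export
encode_hp <- function(hp) {
  stopifnot(inherits(hp, "hp_vector"))
  c(hp$n_kernels, hp$kernel_size, hp$activation, hp$dropout,
    log10(hp$learning_rate), hp$pool_size)
}

#' Activation identifier for an activation code
#'
#' @param code 0, 1 or 2.
#' @return `"relu"`, `"sigmoid"` or `"tanh"`.
#' @export
activation_name <- function(code) {
  if (length(code) != 1 || !(code %in% 0:2)) {
    stop("activation code must be 0 (ReLU), 1 (sigmoid) or 2 (tanh)",
         call. = FALSE)
  }
  c("relu", "sigmoid", "tanh")[code + 1]
}

#' Render a hyperparameter vector as a one-row report table
#'
#' Columns follow the conventional reporting order delta (filters), s
#' (kernel size), a (activation code), d, eta, m (pooling window).  The
#' dropout column `d` is additionally rendered as the integer index
#' `round(10 * d)` in `d_index`, matching the compact coding used in
#' published hyperparameter tables (0.2 prints as 2); the continuous
#' probability and learning rate are kept alongside.
#'
#' @param hp An `hp_vector`.
#' @param model Optional model label for the first column.
#' @return A one-row data frame.
#' @export
report_row <- function(hp, model = "MFO-1D-CNN") {
  stopifnot(inherits(hp, "hp_vector"))
  data.frame(model = model,
             delta = hp$n_kernels,
             s = hp$kernel_size,
             a = hp$activation,
             d = hp$dropout,
             d_index = as.integer(round_half_away(10 * hp$dropout)),
             eta = hp$learning_rate,
             m = hp$pool_size,
             stringsAsFactors = FALSE)
}

#' @export
print.hp_vector <- function(x, ...) {
  cat(sprintf(paste0("CNN hyperparameters: filters=%d kernel=%d act=%s ",
                     "dropout=%.3g lr=%.3g pool=%d\n"),
              x$n_kernels, x$kernel_size, activation_name(x$activation),
              x$dropout, x$learning_rate, x$pool_size))
  invisible(x)
}
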