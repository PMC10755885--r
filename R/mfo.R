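#' Configuration for the moth-flame optimizer
#'
#' Moth-flame optimization (MFO) is a population metaheuristic in which
#' search agents ("moths") spiral around the best solutions found so far
#' ("flames") while the number of retained flames shrinks linearly to one,
#' concentrating late-stage search around the incumbent best.
#'
#' @param bounds A list of `c(lower, upper)` pairs, one per dimension.
#' @param n_moths Population size (default 20).
#' @param max_iter Maximum number of iterations (default 30).
#' @param spiral_b Logarithmic-spiral shape constant `b` (default 1).
#' @param seed Integer seed controlling all randomness of the run.
#' @param signed_distance If `TRUE`, use the signed coordinate-wise
#'   moth-flame difference in the spiral update instead of the absolute
#'   distance (see [spiral_update()]).
#' @return An object of class `mfo_config`.
#' @export
#' @examples
#' cfg <- mfo_config(bounds = list(c(-5, 5), c(-5, 5)), seed = 1)
mfo_config <- function(bounds, n_moths = 20L, max_iter = 30L, spiral_b = 1,
                       seed = 1L, signed_distance = FALSE) {
  stopifnot(is.list(bounds), length(bounds) >= 1)
  for (b in bounds) {
    if (length(b) != 2 || !is.numeric(b) || !(b[1] < b[2])) {
      stop("each bound must be a numeric pair with lower < upper", call. = FALSE)
    }
  }
  if (n_moths < 1) stop("n_moths must be >= 1", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  structure(
    list(bounds = bounds, n_moths = as.integer(n_moths),
         max_iter = as.integer(max_iter), spiral_b = spiral_b,
         seed = as.integer(seed), signed_distance = isTRUE(signed_distance)),
    class = "mfo_config")
}

bounds_matrix <- function(bounds) {
  m <- do.call(rbind, bounds)
  colnames(m) <- c("lower", "upper")
  m
}

clip_to_bounds <- function(positions, bounds) {
  bm <- bounds_matrix(bounds)
  for (j in seq_len(ncol(positions))) {
    positions[, j] <- pmin(pmax(positions[, j], bm[j, 1]), bm[j, 2])
  }
  positions
}

#' Initialize a moth population uniformly within bounds
#'
#' Draws each coordinate independently and uniformly within its declared
#' bound pair, using the seed recorded in the configuration, so two calls
#' with the same configuration return the same matrix.
#'
#' @param config An [mfo_config()] object.
#' @return A list with `positions` (`n_moths` x `d` matrix) and `fitness`
#'   (vector of `NA` until evaluated).
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "mfo_config"))
  d <- length(config$bounds)
  bm <- bounds_matrix(config$bounds)
  positions <- with_seed(config$seed, {
    matrix(runif(config$n_moths * d), nrow = config$n_moths, ncol = d)
  })
  for (j in seq_len(d)) {
    positions[, j] <- bm[j, 1] + positions[, j] * (bm[j, 2] - bm[j, 1])
  }
  list(positions = positions, fitness = rep(NA_real_, config$n_moths))
}

#' Adaptive flame count
#'
#' The number of flames retained at iteration `t` of `t_max`, shrinking
#' linearly from `n_max` to 1: `round(n_max - t * (n_max - 1) / t_max)`,
#' rounded half away from zero and clamped to at least 1.
#'
#' @param t Current iteration (1-based).
#' @param t_max Maximum number of iterations.
#' @param n_max Maximum number of flames (usually the population size).
#' @return A positive integer count.
#' @export
#' @examples
#' flame_count(1, 30, 20)   # 19
#' flame_count(30, 30, 20)  # 1
flame_count <- function(t, t_max, n_max) {
  if (t < 1 || t > t_max) stop("t must lie in 1..t_max", call. = FALSE)
  if (n_max < 1) stop("n_max must be >= 1", call. = FALSE)
  max(1L, as.integer(round_half_away(n_max - t * (n_max - 1) / t_max)))
}

#' Logarithmic-spiral position update
#'
#' Moves a moth along a logarithmic spiral around a flame:
#' `D * exp(b * t) * cos(2 * pi * t) + flame`, applied coordinate-wise,
#' where `D` is the coordinate-wise absolute distance `|moth - flame|`
#' (or the signed difference when `signed = TRUE`).  `t = -1` is the
#' position closest to the flame, `t = 1` the farthest.
#'
#' @param moth,flame Numeric vectors of equal length.
#' @param b Spiral shape constant.
#' @param t Spiral parameter in `[-1, 1]` (scalar or per-coordinate vector).
#' @param signed Use the signed difference for `D`.
#' @return The updated position (not yet clipped to bounds).
#' @export
spiral_update <- function(moth, flame, b = 1, t, signed = FALSE) {
  if (length(moth) != length(flame)) {
    stop("moth and flame must have the same dimension", call. = FALSE)
  }
  d <- moth - flame
  if (!signed) d <- abs(d)
  d * exp(b * t) * cos(2 * pi * t) + flame
}

#' Merge moths into the flame set
#'
#' Pools the current moth records with the previous flames and keeps the
#' `flame_no` best by fitness, sorted ascending.  Because the previous
#' best always takes part in the pool, the global best is never lost
#' (elitism).
#'
#' @param positions Moth position matrix.
#' @param fitness Moth fitness vector (lower is better).
#' @param prev_positions,prev_fitness Previous flame set (may be `NULL`
#'   on the first iteration).
#' @param flame_no Number of flames to keep.
#' @return A list with sorted `positions` and `fitness`.
#' @export
update_flames <- function(positions, fitness, prev_positions = NULL,
                          prev_fitness = NULL, flame_no) {
  if (flame_no < 1) stop("flame_no must be >= 1", call. = FALSE)
  pool_pos <- positions
  pool_fit <- fitness
  if (!is.null(prev_positions)) {
    pool_pos <- rbind(pool_pos, prev_positions)
    pool_fit <- c(pool_fit, prev_fitness)
  }
  ord <- order(pool_fit)
  keep <- ord[seq_len(min(flame_no, length(ord)))]
  list(positions = pool_pos[keep, , drop = FALSE], fitness = pool_fit[keep])
}

#' Run moth-flame optimization
#'
#' Minimizes `objective` over the bounded domain declared in `config`.
#' Each iteration evaluates the population, merges it into the sorted
#' flame set, shrinks the flame count adaptively, and spiral-moves every
#' moth toward its paired flame (moth `i` pairs with flame `i`; moths
#' beyond the current flame count pair with the last kept flame), with
#' the spiral parameter drawn i.i.d. uniform on `[-1, 1]` per coordinate.
#' Positions are clipped to the bounds after every move.  Non-finite
#' objective values are recorded as `+Inf` so a failed evaluation never
#' becomes a flame.
#'
#' @param objective A function taking a `d`-vector and returning a scalar
#'   (lower is better).
#' @param config An [mfo_config()] object.
#' @return An object of class `mfo_result`: `best_position`,
#'   `best_fitness`, and a per-iteration `trace` data frame with columns
#'   `iteration`, `flame_count`, `best_fitness`, `mean_fitness`, and the
#'   best position coordinates.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- run_mfo(sphere, mfo_config(list(c(-5, 5), c(-5, 5)),
#'                                   n_moths = 10, max_iter = 20, seed = 7))
#' res$best_fitness
run_mfo <- function(objective, config) {
  stopifnot(inherits(config, "mfo_config"), is.function(objective))
  d <- length(config$bounds)
  n <- config$n_moths
  t_max <- config$max_iter
  pop <- init_population(config)
  positions <- pop$positions
  flames <- NULL
  trace <- vector("list", t_max)
  with_seed(derive_seed(config$seed, "mfo-loop"), {
    for (t in seq_len(t_max)) {
      positions <- clip_to_bounds(positions, config$bounds)
      fitness <- apply(positions, 1, function(x) {
        v <- objective(x)
        if (!is.finite(v)) Inf else v
      })
      n_flames <- flame_count(t, t_max, n)
      flames <- update_flames(positions, fitness,
                              flames$positions, flames$fitness, n_flames)
      trace[[t]] <- data.frame(
        iteration = t, flame_count = n_flames,
        best_fitness = flames$fitness[1],
        mean_fitness = mean(fitness[is.finite(fitness)]))
      trace[[t]] <- cbind(
        trace[[t]],
        as.data.frame(matrix(flames$positions[1, ], nrow = 1,
                             dimnames = list(NULL, paste0("x", seq_len(d))))))
      for (i in seq_len(n)) {
        j <- min(i, n_flames)
        tv <- runif(d, -1, 1)
        positions[i, ] <- spiral_update(positions[i, ], flames$positions[j, ],
                                        b = config$spiral_b, t = tv,
                                        signed = config$signed_distance)
      }
    }
  })
  structure(
    list(best_position = as.numeric(flames$positions[1, ]),
         best_fitness = flames$fitness[1],
         trace = do.call(rbind, trace),
         config = config),
    class = "mfo_result")
}

#' @export
print.mfo_result <- function(x, ...) {
  cat("Moth-flame optimization result\n")
  cat(sprintf("  iterations: %d, population: %d\n",
              x$config$max_iter, x$config$n_moths))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  cat("  best position:", format(x$best_position, digits = 4), "\n")
  invisible(x)
}

#' Write an optimization trace as a delimited table
#'
#' @param result An `mfo_result`.
#' @param path Output file path (tab-separated).
#' @return The path, invisibly.
#' @export
write_mfo_trace <- function(result, path) {
  stopifnot(inherits(result, "mfo_result"))
  write.table(result$trace, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
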