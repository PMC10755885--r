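#' Split one EEG segment into fixed-length non-overlapping chunks
#'
#' Cuts the sequence into `floor(length(x) / chunk_len)` consecutive
#' chunks starting at the first sample; any trailing remainder shorter
#' than `chunk_len` is discarded.  Concatenating the chunks reproduces
#' the corresponding prefix of the input exactly.
#'
#' @param x Numeric sample vector (or an `eeg_segment`).
#' @param chunk_len Chunk length in samples (default 178, one second at
#'   the Bonn sampling rate rounded to match the network input length).
#' @return A list of numeric chunks, possibly empty.
#' @export
#' @examples
#' length(window_segment(rnorm(4097), 178))  # 23
window_segment <- function(x, chunk_len = 178L) {
  if (inherits(x, "eeg_segment")) x <- x$samples
  stopifnot(is.numeric(x), chunk_len >= 1)
  n <- floor(length(x) / chunk_len)
  if (n == 0) {
    warning("segment shorter than chunk_len; no chunks produced")
    return(list())
  }
  lapply(seq_len(n), function(i) x[((i - 1) * chunk_len + 1):(i * chunk_len)])
}

#' Assemble a windowed dataset from labeled EEG subsets
#'
#' Windows every segment of every subset with [window_segment()] and
#' stacks the chunks into one matrix.  Labels are assigned by subset
#' position in the order given (conventionally A..E map to 0..4).  The
#' originating subset letter and segment index of every row are
#' retained so splits can optionally be made at segment granularity.
#'
#' @param subsets A named list of subsets; each subset is a list of
#'   numeric segments (or `eeg_segment`s).  Names default to `A`, `B`,
#'   ... in order.
#' @param chunk_len Chunk length in samples.
#' @return An object of class `windowed_dataset`: `X` (chunks x
#'   `chunk_len` matrix), `y` (integer labels 0-based), `subset`
#'   (character), `segment` (integer id, unique across subsets), and
#'   `chunk_len`.
#' @export
build_windowed_dataset <- function(subsets, chunk_len = 178L) {
  stopifnot(is.list(subsets), length(subsets) >= 1)
  if (is.null(names(subsets)) || any(names(subsets) == "")) {
    names(subsets) <- LETTERS[seq_along(subsets)]
  }
  rows <- list()
  y <- integer(0)
  subset_lab <- character(0)
  segment_id <- integer(0)
  seg_counter <- 0L
  for (k in seq_along(subsets)) {
    segs <- subsets[[k]]
    for (s in seq_along(segs)) {
      seg <- segs[[s]]
      if (inherits(seg, "eeg_segment")) seg <- seg$samples
      if (length(seg) < chunk_len) {
        stop(sprintf("segment %d of subset %s has %d samples (< chunk_len %d)",
                     s, names(subsets)[k], length(seg), chunk_len),
             call. = FALSE)
      }
      chunks <- window_segment(seg, chunk_len)
      seg_counter <- seg_counter + 1L
      rows[[length(rows) + 1L]] <- do.call(rbind, chunks)
      y <- c(y, rep.int(k - 1L, length(chunks)))
      subset_lab <- c(subset_lab, rep.int(names(subsets)[k], length(chunks)))
      segment_id <- c(segment_id, rep.int(seg_counter, length(chunks)))
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("X", seq_len(chunk_len))
  structure(list(X = X, y = y, subset = subset_lab, segment = segment_id,
                 chunk_len = as.integer(chunk_len)),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("Windowed EEG dataset: %d chunks x %d samples, %d class(es)\n",
              nrow(x$X), x$chunk_len, length(unique(x$y))))
  print(table(label = x$y))
  invisible(x)
}

ds_take <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
                 subset = ds$subset[idx], segment = ds$segment[idx],
                 chunk_len = ds$chunk_len),
            class = "windowed_dataset")
}

#' Stratified train/test split of a windowed dataset
#'
#' Shuffles within each class with the given seed and assigns
#' `round(train_fraction * class size)` rows of every class to the
#' training portion, so train and test class proportions match the
#' global proportions to within one row.  With `by_segment = TRUE` whole
#' source segments are assigned to one side only, preventing chunk-level
#' leakage between splits.
#'
#' @param ds A `windowed_dataset`.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed for the shuffle.
#' @param by_segment Split at source-segment rather than chunk
#'   granularity (default `FALSE`).
#' @return A list with `train` and `test` `windowed_dataset`s.
#' @export
split_dataset <- function(ds, train_fraction = 0.8, seed = 1L,
                          by_segment = FALSE) {
  stopifnot(inherits(ds, "windowed_dataset"),
            train_fraction > 0, train_fraction <= 1)
  classes <- sort(unique(ds$y))
  if (any(tabulate(ds$y + 1L) == 0)) stop("empty class", call. = FALSE)
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in classes) {
      if (by_segment) {
        segs <- unique(ds$segment[ds$y == cl])
        if (length(segs) < 2) {
          stop("by_segment split needs >= 2 segments per class", call. = FALSE)
        }
        segs <- sample(segs)
        n_tr <- round(train_fraction * length(segs))
        take <- segs[seq_len(n_tr)]
        train_idx <- c(train_idx, which(ds$y == cl & ds$segment %in% take))
      } else {
        idx <- which(ds$y == cl)
        if (length(idx) < 2 && train_fraction < 1) {
          stop("each class needs >= 2 rows to split", call. = FALSE)
        }
        idx <- sample(idx)
        n_tr <- round(train_fraction * length(idx))
        train_idx <- c(train_idx, idx[seq_len(n_tr)])
      }
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(ds$y), train_idx)
  list(train = ds_take(ds, train_idx), test = ds_take(ds, test_idx))
}

#' Stratified k-fold cross-validation indices
#'
#' Assigns the rows of every class to `k` folds of as-equal-as-possible
#' size (per-class fold sizes differ by at most one), after a seeded
#' within-class shuffle.  Folds are pairwise disjoint and exhaustive.
#'
#' @param y Integer label vector.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of `k` integer index vectors.
#' @export
kfold_indices <- function(y, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  classes <- unique(y)
  for (cl in classes) {
    if (sum(y == cl) < k) {
      stop(sprintf("class %s has fewer rows than k = %d", cl, k),
           call. = FALSE)
    }
  }
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      assignment <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[assignment == f])
      }
    }
  })
  lapply(folds, sort)
}

parse_groups <- function(groups) {
  parts <- strsplit(groups, "vs", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) < 2) {
    stop("group expression must name at least two groups, e.g. \"A vs E\"",
         call. = FALSE)
  }
  groups_list <- lapply(parts, function(p) {
    letters_in <- strsplit(gsub("[^A-E]", "", toupper(p)), "")[[1]]
    if (length(letters_in) == 0) {
      stop(sprintf("group '%s' references no subset A-E", p), call. = FALSE)
    }
    unique(letters_in)
  })
  all_letters <- unlist(groups_list)
  if (anyDuplicated(all_letters)) {
    stop("groups must be disjoint subsets of A-E", call. = FALSE)
  }
  groups_list
}

#' Select and relabel subsets for a sub-experiment
#'
#' Interprets expressions like `"A vs E"` or `"AB vs CDE"`: rows whose
#' originating subset is not referenced are dropped, and each group is
#' relabeled `0 .. G-1` in the order written.  This supports the usual
#' two- to five-class seizure detection sub-experiments, including
#' imbalanced groupings.
#'
#' @param ds A `windowed_dataset` built from lettered subsets.
#' @param groups A group expression string.
#' @return A relabeled `windowed_dataset`.
#' @export
#' @examples
#' \dontrun{subset_selector(ds, "AB vs CDE")}
subset_selector <- function(ds, groups) {
  stopifnot(inherits(ds, "windowed_dataset"))
  gl <- parse_groups(groups)
  keep <- ds$subset %in% unlist(gl)
  out <- ds_take(ds, which(keep))
  newy <- integer(length(out$y))
  for (g in seq_along(gl)) {
    newy[out$subset %in% gl[[g]]] <- g - 1L
  }
  out$y <- newy
  out
}

#' Write a windowed dataset as a delimited table
#'
#' One row per chunk: sample columns `X1..X<chunk_len>` then the label
#' column `y` and the bookkeeping columns `subset` and `segment`.
#'
#' @param ds A `windowed_dataset`.
#' @param path Output path (tab-separated).
#' @return The path, invisibly.
#' @export
write_windowed_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "windowed_dataset"))
  df <- as.data.frame(ds$X)
  df$y <- ds$y
  df$subset <- ds$subset
  df$segment <- ds$segment
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a windowed dataset written by [write_windowed_dataset()]
#'
#' @param path Input path.
#' @return A `windowed_dataset`.
#' @export
read_windowed_dataset <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  xcols <- grep("^X[0-9]+$", names(df))
  X <- as.matrix(df[, xcols])
  structure(list(X = X, y = as.integer(df$y),
                 subset = if ("subset" %in% names(df)) df$subset else
                   rep(NA_character_, nrow(df)),
                 segment = if ("segment" %in% names(df))
                   as.integer(df$segment) else seq_len(nrow(df)),
                 chunk_len = length(xcols)),
            class = "windowed_dataset")
}
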