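#' Read one Bonn-format EEG segment file
#'
#' The Bonn University corpus stores each single-channel segment as a
#' plain-text file with one numeric sample (microvolts) per line; a
#' complete segment holds 4097 samples recorded at 173.61 Hz.
#'
#' @param path File path.
#' @param fs Sampling rate attached to the segment (default 173.61 Hz).
#' @param expected_samples Expected sample count (default 4097).
#' @param strict Error (rather than warn) when the count differs.
#' @param subset_label Optional subset letter to attach.
#' @return An `eeg_segment`.
#' @export
read_segment_file <- function(path, fs = 173.61, expected_samples = 4097L,
                              strict = FALSE, subset_label = NA_character_) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop(sprintf("empty segment file: %s", path), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1]
    stop(sprintf("non-numeric sample at line %d of %s: '%s'",
                 bad, path, lines[bad]), call. = FALSE)
  }
  if (!is.null(expected_samples) && length(x) != expected_samples) {
    msg <- sprintf("%s has %d samples (expected %d)", path, length(x),
                   expected_samples)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(samples = x, sampling_rate = fs,
                 subset_label = subset_label),
            class = "eeg_segment")
}

# The public corpus names its subsets Z, O, N, F, S; they are usually
# referred to as A..E.  Accept either spelling of the folder name.
BONN_FOLDER_ALIASES <- list(A = c("A", "Z"), B = c("B", "O"),
                            C = c("C", "N"), D = c("D", "F"),
                            E = c("E", "S"))

#' Load Bonn-layout EEG subsets from a directory tree
#'
#' Expects one folder per subset under `root`, named by either the A-E
#' or the original Z/O/N/F/S convention, holding one text file per
#' segment.  Files are read in lexicographic order so the resulting
#' dataset row order is reproducible regardless of filesystem listing
#' order.
#'
#' @param root Corpus root directory.
#' @param wanted Subset letters to load (default all five).
#' @param strict Passed to [read_segment_file()].
#' @return A named list of segment lists, one entry per wanted subset.
#' @export
load_subsets <- function(root, wanted = c("A", "B", "C", "D", "E"),
                         strict = FALSE) {
  stopifnot(dir.exists(root))
  out <- list()
  for (lab in wanted) {
    if (!lab %in% names(BONN_FOLDER_ALIASES)) {
      stop(sprintf("unknown subset label '%s'", lab), call. = FALSE)
    }
    cand <- file.path(root, BONN_FOLDER_ALIASES[[lab]])
    subdir <- cand[dir.exists(cand)][1]
    if (is.na(subdir)) {
      stop(sprintf("subset folder for '%s' not found under %s", lab, root),
           call. = FALSE)
    }
    files <- sort(list.files(subdir, pattern = "\\.(txt|TXT)$",
                             full.names = TRUE))
    if (length(files) == 0) {
      stop(sprintf("no segment files in %s", subdir), call. = FALSE)
    }
    out[[lab]] <- lapply(files, read_segment_file, strict = strict,
                         subset_label = lab)
  }
  out
}

#' Manifest of a Bonn-layout corpus directory
#'
#' @param root Corpus root directory.
#' @return A data frame: `subset`, `filename`, `n_samples`, `checksum`
#'   (MD5), in lexicographic file order.
#' @export
corpus_manifest <- function(root) {
  subs <- Filter(function(d) dir.exists(file.path(root, d)),
                 list.files(root))
  rows <- list()
  for (lab in sort(subs)) {
    files <- sort(list.files(file.path(root, lab),
                             pattern = "\\.(txt|TXT)$", full.names = TRUE))
    for (f in files) {
      n <- length(readLines(f, warn = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        subset = lab, filename = basename(f), n_samples = n,
        checksum = unname(tools::md5sum(f)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
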