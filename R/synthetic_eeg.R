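#' Default generation recipes for the five synthetic EEG classes
#'
#' The recipes are phenomenological: each class is colored background
#' noise plus class-discriminative structure, on the amplitude scale of
#' scalp/intracranial EEG in microvolts.  A and B emulate awake healthy
#' recordings (alpha-band 8-13 Hz rhythm, stronger with eyes closed in
#' B); C and D emulate interictal recordings with Poisson-timed sharp
#' spikes (higher rate in D); E emulates ictal activity as
#' high-amplitude 3-7 Hz oscillation whose peaks exceed 1000 uV, an
#' order of magnitude above the other classes (around the 100 uV scale).
#'
#' @return A named list of per-class parameter lists.
#' @export
class_recipes <- function() {
  list(
    A = list(noise_sd = 30, alpha_amp = 12, alpha_freq = 10,
             slow_amp = 15, spike_rate = 0, spike_amp = 0,
             burst_amp = 0, burst_freq = 0),
    B = list(noise_sd = 30, alpha_amp = 55, alpha_freq = 10,
             slow_amp = 15, spike_rate = 0, spike_amp = 0,
             burst_amp = 0, burst_freq = 0),
    C = list(noise_sd = 40, alpha_amp = 10, alpha_freq = 9,
             slow_amp = 30, spike_rate = 0.6, spike_amp = 220,
             burst_amp = 0, burst_freq = 0),
    D = list(noise_sd = 40, alpha_amp = 10, alpha_freq = 9,
             slow_amp = 30, spike_rate = 2.2, spike_amp = 260,
             burst_amp = 0, burst_freq = 0),
    E = list(noise_sd = 60, alpha_amp = 0, alpha_freq = 10,
             slow_amp = 0, spike_rate = 0, spike_amp = 0,
             burst_amp = 1250, burst_freq = 5))
}

# Interpolate a recipe toward the A (featureless-background) recipe:
# separability 1 returns the recipe unchanged, 0 collapses every class
# onto A so that no class-discriminative structure remains.
blend_recipe <- function(recipe, base, separability) {
  out <- recipe
  for (f in names(recipe)) {
    out[[f]] <- base[[f]] + separability * (recipe[[f]] - base[[f]])
  }
  out
}

# AR(1)-colored Gaussian background noise scaled to a target sd
colored_noise <- function(n, sd_target, phi = 0.85) {
  x <- as.numeric(filter(rnorm(n), phi, method = "recursive"))
  x * sd_target / sd(x)
}

# biphasic interictal spike template, ~70 ms half-width at fs
spike_template <- function(fs) {
  t <- seq(-0.1, 0.15, by = 1 / fs)
  w <- exp(-(t / 0.02)^2) - 0.45 * exp(-((t - 0.06) / 0.05)^2)
  w / max(abs(w))
}

synth_segment <- function(recipe, n_samples, fs) {
  t <- (seq_len(n_samples) - 1) / fs
  x <- colored_noise(n_samples, recipe$noise_sd)
  if (recipe$slow_amp > 0) {
    x <- x + recipe$slow_amp * sin(2 * pi * runif(1, 0.5, 2.5) * t +
                                   runif(1, 0, 2 * pi))
  }
  if (recipe$alpha_amp > 0) {
    x <- x + recipe$alpha_amp *
      sin(2 * pi * (recipe$alpha_freq + runif(1, -1, 1)) * t +
          runif(1, 0, 2 * pi))
  }
  if (recipe$spike_rate > 0 && recipe$spike_amp > 0) {
    tpl <- spike_template(fs)
    n_spikes <- rpois(1, recipe$spike_rate * n_samples / fs)
    if (n_spikes > 0) {
      starts <- sort(sample.int(max(n_samples - length(tpl), 1), n_spikes,
                                replace = TRUE))
      for (s in starts) {
        span <- s:min(s + length(tpl) - 1, n_samples)
        pol <- sample(c(-1, 1), 1)
        amp <- recipe$spike_amp * runif(1, 0.7, 1.3)
        x[span] <- x[span] + pol * amp * tpl[seq_along(span)]
      }
    }
  }
  if (recipe$burst_amp > 0) {
    f <- recipe$burst_freq + runif(1, -2, 2)
    amp <- recipe$burst_amp * runif(1, 0.95, 1.15)
    env <- 1 + 0.08 * sin(2 * pi * runif(1, 0.1, 0.4) * t +
                          runif(1, 0, 2 * pi))
    x <- x + amp * env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  x
}

#' Generate one synthetic EEG subset
#'
#' Segments are drawn from the class recipe (see [class_recipes()]),
#' optionally blended toward the featureless background recipe by the
#' `separability` factor, and quantized to integer microvolts to mirror
#' the ASCII layout of the Bonn corpus.  All randomness flows from one
#' seeded generator, so a repeated call is bit-identical.
#'
#' @param label Subset letter `A`..`E`.
#' @param n_segments Number of segments (default 100).
#' @param n_samples Samples per segment (default 4097).
#' @param fs Sampling rate in Hz (default 173.61).
#' @param seed Integer seed.
#' @param separability Scale of inter-class differences in `[0, 1]`
#'   (default 1); at 0 every class reduces to the background recipe.
#' @param quantize Round samples to integer microvolts (default `TRUE`).
#' @return A list of `eeg_segment` objects (fields `samples`,
#'   `sampling_rate`, `subset_label`).
#' @export
generate_subset <- function(label, n_segments = 100L, n_samples = 4097L,
                            fs = 173.61, seed = 1L, separability = 1,
                            quantize = TRUE) {
  recipes <- class_recipes()
  if (!label %in% names(recipes)) {
    stop("label must be one of A, B, C, D, E", call. = FALSE)
  }
  recipe <- blend_recipe(recipes[[label]], recipes$A, separability)
  with_seed(derive_seed(seed, paste0("subset-", label)), {
    lapply(seq_len(n_segments), function(i) {
      x <- synth_segment(recipe, n_samples, fs)
      if (quantize) x <- round(x)
      structure(list(samples = x, sampling_rate = fs, subset_label = label),
                class = "eeg_segment")
    })
  })
}

#' Generate a full five-class synthetic EEG corpus
#'
#' Bonn-shaped by default: five subsets of 100 segments of 4097 samples
#' at 173.61 Hz, which windows into 11,500 one-second chunks of 178
#' samples.
#'
#' @inheritParams generate_subset
#' @param subsets Which subsets to generate (default all five).
#' @return An object of class `eeg_corpus`: a named list of subsets
#'   plus generation metadata.
#' @export
#' @examples
#' corpus <- generate_corpus(n_segments = 2, seed = 1)
#' sapply(corpus$subsets, length)
generate_corpus <- function(n_segments = 100L, n_samples = 4097L,
                            fs = 173.61, seed = 1L, separability = 1,
                            subsets = c("A", "B", "C", "D", "E"),
                            quantize = TRUE) {
  subs <- lapply(subsets, function(lab) {
    generate_subset(lab, n_segments = n_segments, n_samples = n_samples,
                    fs = fs, seed = seed, separability = separability,
                    quantize = quantize)
  })
  names(subs) <- subsets
  structure(list(subsets = subs, seed = as.integer(seed),
                 separability = separability, fs = fs,
                 n_segments = as.integer(n_segments),
                 n_samples = as.integer(n_samples)),
            class = "eeg_corpus")
}

#' @export
print.eeg_corpus <- function(x, ...) {
  cat(sprintf("Synthetic EEG corpus: %d subset(s) x %d segments x %d samples @ %.2f Hz\n",
              length(x$subsets), x$n_segments, x$n_samples, x$fs))
  cat(sprintf("  seed %d, separability %.2f\n", x$seed, x$separability))
  invisible(x)
}

#' Export a corpus in the Bonn ASCII directory layout
#'
#' One directory per subset letter; one file per segment
#' (`<letter>001.txt` ...) with one integer sample per line, so
#' [read_segment_file()] and [load_subsets()] round-trip the corpus.
#'
#' @param corpus An `eeg_corpus`.
#' @param dir Output directory (created if missing).
#' @param force Overwrite an existing non-empty directory.
#' @return The directory path, invisibly.
#' @export
export_corpus <- function(corpus, dir, force = FALSE) {
  stopifnot(inherits(corpus, "eeg_corpus"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)", dir),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (lab in names(corpus$subsets)) {
    subdir <- file.path(dir, lab)
    dir.create(subdir, showWarnings = FALSE)
    segs <- corpus$subsets[[lab]]
    for (i in seq_along(segs)) {
      fn <- file.path(subdir, sprintf("%s%03d.txt", lab, i))
      writeLines(format(segs[[i]]$samples, scientific = FALSE,
                        trim = TRUE), fn)
      manifest[[length(manifest) + 1L]] <- data.frame(
        subset = lab, filename = basename(fn),
        n_samples = length(segs[[i]]$samples),
        checksum = unname(tools::md5sum(fn)),
        stringsAsFactors = FALSE)
    }
  }
  mdf <- do.call(rbind, manifest)
  write.table(mdf, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
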