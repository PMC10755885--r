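# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

# five-class miniature corpus: 4 segments per subset
tiny_corpus <- function() {
  fixture("tiny_corpus", generate_corpus(n_segments = 4, seed = 101))
}

tiny_ds <- function() {
  fixture("tiny_ds", build_windowed_dataset(tiny_corpus()$subsets))
}

# two-class (healthy vs ictal) miniature dataset: 6 segments per subset
ae_ds <- function() {
  fixture("ae_ds", {
    corpus <- generate_corpus(n_segments = 6, seed = 202,
                              subsets = c("A", "E"))
    build_windowed_dataset(corpus$subsets)
  })
}

# the published optimized hyperparameter vector and its architecture
table2_hp <- function() hp_vector(50L, 10L, 0L, 0.2, 1e-3, 2L)

table2_spec <- function() {
  fixture("table2_spec", infer_shapes(build_model_spec(table2_hp())))
}

# a fast run configuration for pipeline-level tests
mini_config <- function() {
  cfg <- default_run_config()
  cfg$synth.n_segments <- 2L
  cfg$mfo.n_moths <- 2L
  cfg$mfo.max_iter <- 2L
  cfg$fitness.search_epochs <- 1L
  cfg$fitness.batch_size <- 32L
  cfg$train.epochs <- 2L
  cfg$train.batch_size <- 32L
  cfg
}

# manifest stripped of wall-clock fields for reproducibility comparisons
manifest_fingerprint <- function(path) {
  m <- jsonlite::read_json(path)
  m$timings_secs <- NULL
  m
}
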