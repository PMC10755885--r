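#' Default flat run configuration
#'
#' Every tunable default of the pipeline in one flat key-value list,
#' overridable from a YAML file via [read_run_config()].  Keys are
#' namespaced by stage: `synth.*` (corpus generation), `window.*`
#' (segmentation), `split.*` (train/test partitioning), `mfo.*`
#' (optimizer), `fitness.*` (short-budget objective), `train.*` (final
#' training), `model.*` (architecture).
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(
    synth.n_segments = 100L, synth.n_samples = 4097L, synth.fs = 173.61,
    synth.separability = 1,
    window.chunk_len = 178L,
    split.train_fraction = 0.8, split.by_segment = FALSE,
    mfo.n_moths = 20L, mfo.max_iter = 30L, mfo.spiral_b = 1,
    fitness.search_epochs = 10L, fitness.batch_size = 32L,
    fitness.max_train_rows = Inf,
    train.batch_size = 256L, train.epochs = 500L, train.val_fraction = 0.1,
    model.n_blocks = 6L)
}

#' Read a flat YAML run configuration
#'
#' Unknown keys are rejected; given keys override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file of flat `key: value` pairs.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(defaults, user)
}

#' Generate and export a synthetic corpus (pipeline stage)
#'
#' @param out_dir Output directory for the Bonn-layout ASCII corpus.
#' @param seed Global seed (the stage derives its own stream from it).
#' @param config A run configuration list.
#' @param subsets Subset letters to generate.
#' @param force Overwrite an existing non-empty directory.
#' @return The corpus (invisibly); files and a manifest are written
#'   under `out_dir`.
#' @export
cmd_synth <- function(out_dir, seed = 1L, config = default_run_config(),
                      subsets = c("A", "B", "C", "D", "E"), force = FALSE) {
  corpus <- generate_corpus(
    n_segments = config$synth.n_segments,
    n_samples = config$synth.n_samples,
    fs = config$synth.fs,
    seed = derive_seed(seed, "synth"),
    separability = config$synth.separability,
    subsets = subsets)
  export_corpus(corpus, out_dir, force = force)
  invisible(corpus)
}

#' Window a corpus directory into a dataset file (pipeline stage)
#'
#' @param input_dir Bonn-layout corpus directory.
#' @param out_file Output dataset path (tab-separated).
#' @param config A run configuration list.
#' @param subsets Subset letters to load.
#' @return The `windowed_dataset` (invisibly).
#' @export
cmd_window <- function(input_dir, out_file = NULL,
                       config = default_run_config(),
                       subsets = c("A", "B", "C", "D", "E")) {
  present <- subsets[vapply(subsets, function(lab) {
    any(dir.exists(file.path(input_dir, BONN_FOLDER_ALIASES[[lab]])))
  }, logical(1))]
  if (length(present) == 0) {
    stop(sprintf("no subset folders found under %s", input_dir),
         call. = FALSE)
  }
  segs <- load_subsets(input_dir, wanted = present)
  ds <- build_windowed_dataset(segs, chunk_len = config$window.chunk_len)
  if (!is.null(out_file)) write_windowed_dataset(ds, out_file)
  invisible(ds)
}

#' Optimize CNN hyperparameters for a dataset (pipeline stage)
#'
#' Runs moth-flame optimization over the six-dimensional hyperparameter
#' space, scoring each decoded candidate with a short-budget training
#' run ([evaluate_fitness()]) on a stratified train/validation split of
#' the training portion.
#'
#' @param ds A `windowed_dataset` (or path to one).
#' @param seed Global seed.
#' @param config A run configuration list.
#' @return A list: `best_hp` (decoded `hp_vector`), `best_fitness`,
#'   `mfo` (the full `mfo_result`), `spec` (the winning `model_spec`),
#'   `report` (one-row hyperparameter table).
#' @export
cmd_optimize <- function(ds, seed = 1L, config = default_run_config()) {
  if (is.character(ds)) ds <- read_windowed_dataset(ds)
  stopifnot(inherits(ds, "windowed_dataset"))
  if (length(unique(ds$y)) < 2) {
    stop("dataset must contain at least 2 classes", call. = FALSE)
  }
  if (config$fitness.search_epochs < 1) {
    stop("fitness.search_epochs must be >= 1", call. = FALSE)
  }
  sp <- split_dataset(ds, 1 - config$train.val_fraction,
                      seed = derive_seed(seed, "optimize-val"))
  data <- list(train = sp$train, val = sp$test)
  fit_cfg <- fitness_config(search_epochs = config$fitness.search_epochs,
                            batch_size = config$fitness.batch_size,
                            max_train_rows = config$fitness.max_train_rows)
  n_classes <- length(unique(ds$y))
  fitness_seed <- derive_seed(seed, "fitness")
  objective <- function(pos) {
    evaluate_fitness(decode_position(pos), data, fit_cfg,
                     seed = fitness_seed, n_classes = n_classes,
                     n_blocks = config$model.n_blocks)
  }
  mfo_cfg <- mfo_config(bounds = hp_bounds(),
                        n_moths = config$mfo.n_moths,
                        max_iter = config$mfo.max_iter,
                        spiral_b = config$mfo.spiral_b,
                        seed = derive_seed(seed, "mfo"))
  result <- run_mfo(objective, mfo_cfg)
  best_hp <- decode_position(result$best_position)
  spec <- build_model_spec(best_hp, input_len = ds$chunk_len,
                           n_classes = n_classes,
                           n_blocks = config$model.n_blocks)
  list(best_hp = best_hp, best_fitness = result$best_fitness,
       mfo = result, spec = infer_shapes(spec), report = report_row(best_hp))
}

#' Train the final model and evaluate on held-out data (pipeline stage)
#'
#' Splits the dataset 80-20 (stratified), trains at the full budget
#' with best-validation checkpointing, and reports test-set metrics.
#' With `groups`, rows are first restricted and relabeled by the group
#' expression (e.g. `"A vs E"`, `"AB vs CDE"`).  With `cv`, a
#' stratified k-fold cross-validation is run instead and per-fold plus
#' pooled reports are returned.
#'
#' @param ds A `windowed_dataset` (or path).
#' @param hp An `hp_vector` (e.g. from [cmd_optimize()]).
#' @param seed Global seed.
#' @param config A run configuration list.
#' @param groups Optional group expression for sub-experiments.
#' @param cv Optional number of cross-validation folds.
#' @return For a plain run: a list with `report`
#'   (`evaluation_report`), `fit` (the [train_model()] result), and
#'   `test` labels/predictions.  For `cv`: a list with `folds` (list of
#'   reports), `pooled` (report over all held-out folds) and `table`.
#' @export
cmd_train_eval <- function(ds, hp, seed = 1L, config = default_run_config(),
                           groups = NULL, cv = NULL) {
  if (is.character(ds)) ds <- read_windowed_dataset(ds)
  stopifnot(inherits(ds, "windowed_dataset"), inherits(hp, "hp_vector"))
  if (!is.null(groups)) ds <- subset_selector(ds, groups)
  n_classes <- length(unique(ds$y))
  spec <- build_model_spec(hp, input_len = ds$chunk_len,
                           n_classes = n_classes,
                           n_blocks = config$model.n_blocks)
  cfg <- train_config(batch_size = config$train.batch_size,
                      epochs = config$train.epochs,
                      validation_fraction = config$train.val_fraction,
                      seed = derive_seed(seed, "final-train"))
  if (is.null(cv)) {
    sp <- split_dataset(ds, config$split.train_fraction,
                        seed = derive_seed(seed, "test-split"),
                        by_segment = config$split.by_segment)
    fit <- train_model(spec, list(train = sp$train), cfg)
    probs <- predict(fit$model, sp$test)
    pred <- max.col(probs) - 1L
    rep <- evaluation_report(sp$test$y, pred, K = n_classes)
    list(report = rep, fit = fit,
         test = list(truth = sp$test$y, pred = pred))
  } else {
    folds <- kfold_indices(ds$y, k = cv, seed = derive_seed(seed, "cv"))
    all_truth <- integer(0)
    all_pred <- integer(0)
    fold_reports <- vector("list", cv)
    for (f in seq_len(cv)) {
      test_idx <- folds[[f]]
      train <- ds_take(ds, setdiff(seq_along(ds$y), test_idx))
      test <- ds_take(ds, test_idx)
      fold_cfg <- cfg
      fold_cfg$seed <- derive_seed(cfg$seed, paste0("fold-", f))
      fit <- train_model(spec, list(train = train), fold_cfg)
      probs <- predict(fit$model, test)
      pred <- max.col(probs) - 1L
      fold_reports[[f]] <- evaluation_report(test$y, pred, K = n_classes)
      all_truth <- c(all_truth, test$y)
      all_pred <- c(all_pred, pred)
    }
    names(fold_reports) <- paste0("fold", seq_len(cv))
    pooled <- evaluation_report(all_truth, all_pred, K = n_classes)
    tab <- report_table(c(fold_reports, list(pooled = pooled)),
                        group = if (is.null(groups)) "" else groups)
    list(folds = fold_reports, pooled = pooled, table = tab)
  }
}

#' Batch-size sweep on a dataset (pipeline stage)
#'
#' @inheritParams cmd_train_eval
#' @param sizes Batch sizes to sweep.
#' @param epochs Epochs per run.
#' @return The long curve table of [batch_size_sweep()].
#' @export
cmd_sweep_batch <- function(ds, hp, seed = 1L,
                            config = default_run_config(),
                            sizes = c(32L, 64L, 128L, 256L, 512L, 1024L),
                            epochs = 20L) {
  if (is.character(ds)) ds <- read_windowed_dataset(ds)
  spec <- build_model_spec(hp, input_len = ds$chunk_len,
                           n_classes = length(unique(ds$y)),
                           n_blocks = config$model.n_blocks)
  batch_size_sweep(spec, ds, sizes = sizes, epochs = epochs,
                   seed = derive_seed(seed, "sweep"))
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  names(sums) <- basename(paths)  # run directories must compare equal
  as.list(sums)
}

#' Run the full pipeline with one seed and a written manifest
#'
#' Executes synth, window, optimize and train-eval in sequence under
#' `out_dir`, deriving every stage seed from the one global seed, and
#' writes `manifest.json` capturing the configuration snapshot, the
#' seeds, per-stage wall times, and MD5 checksums of every artifact.
#' Two runs with the same seed and configuration produce identical
#' artifacts and checksums.  With `resume = TRUE`, stages whose
#' artifacts already exist are skipped and their outputs re-read.
#'
#' @param out_dir Run directory (created if needed).
#' @param seed Global seed.
#' @param config A run configuration list.
#' @param subsets Subset letters for the corpus.
#' @param groups Optional group expression for the evaluation stage.
#' @param resume Skip stages whose artifacts already exist.
#' @param force Overwrite an existing corpus directory.
#' @return The manifest list (invisibly); artifacts under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = default_run_config(),
                         subsets = c("A", "B", "C", "D", "E"),
                         groups = NULL, resume = FALSE, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus_dir <- file.path(out_dir, "corpus")
  dataset_file <- file.path(out_dir, "dataset.tsv")
  trace_file <- file.path(out_dir, "mfo_trace.tsv")
  hp_file <- file.path(out_dir, "best_hyperparameters.tsv")
  spec_file <- file.path(out_dir, "model_spec.tsv")
  report_file <- file.path(out_dir, "evaluation.tsv")
  timings <- list()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr  # lazy argument evaluated here
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }

  if (!(resume && dir.exists(corpus_dir) &&
        file.exists(file.path(corpus_dir, "manifest.tsv")))) {
    st <- tic(cmd_synth(corpus_dir, seed = seed, config = config,
                        subsets = subsets, force = force || resume))
    timings$synth <- st$secs
  }
  if (!(resume && file.exists(dataset_file))) {
    st <- tic(cmd_window(corpus_dir, dataset_file, config = config,
                         subsets = subsets))
    ds <- st$value
    timings$window <- st$secs
  } else {
    ds <- read_windowed_dataset(dataset_file)
  }
  if (!is.null(groups)) ds <- subset_selector(ds, groups)

  if (!(resume && file.exists(hp_file) && file.exists(trace_file))) {
    st <- tic(cmd_optimize(ds, seed = seed, config = config))
    opt <- st$value
    timings$optimize <- st$secs
    write_mfo_trace(opt$mfo, trace_file)
    write.table(opt$report, hp_file, sep = "\t", row.names = FALSE,
                quote = FALSE)
    write_model_spec(opt$spec, spec_file)
    best_hp <- opt$best_hp
  } else {
    row <- read.table(hp_file, header = TRUE, sep = "\t")
    best_hp <- hp_vector(row$delta, row$s, row$a, row$d, row$eta, row$m)
  }

  if (!(resume && file.exists(report_file))) {
    st <- tic(cmd_train_eval(ds, best_hp, seed = seed, config = config))
    ev <- st$value
    timings$train_eval <- st$secs
    tab <- report_table(list(run = ev$report),
                        group = if (is.null(groups)) "all" else groups)
    write.table(tab, report_file, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mfocnn")),
    seed = seed,
    stage_seeds = list(synth = derive_seed(seed, "synth"),
                       mfo = derive_seed(seed, "mfo"),
                       fitness = derive_seed(seed, "fitness"),
                       final_train = derive_seed(seed, "final-train")),
    config = config,
    groups = groups,
    subsets = subsets,
    artifacts = file_checksums(c(dataset_file, trace_file, hp_file,
                                 spec_file, report_file,
                                 file.path(corpus_dir, "manifest.tsv"))),
    timings_secs = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
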