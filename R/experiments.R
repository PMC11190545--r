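# Experiment drivers: the benchmark validation suite (best / mean / sd
# over repeated seeded runs per objective and algorithm) and the
# end-to-end classification experiment (oversample -> split ->
# augment(train) -> standardize -> encode -> train -> metrics).

#' Run the benchmark validation suite
#'
#' Runs each algorithm `runs` times on each objective with
#' deterministically derived per-run seeds and summarizes best-over-runs,
#' mean-over-runs and the standard deviation, in canonical suite order.
#'
#' @param functions Objective names (default all of [bench_names()]).
#' @param algorithms Subset of `c("ngo", "ngo-lc")`.
#' @param runs Repetitions per cell (default 20).
#' @param n Population size (default 100).
#' @param iterations Iterations per run (default 900).
#' @param dimension Problem dimension (default 30).
#' @param seed Master seed from which all per-run seeds derive.
#' @param fast Use the reduced CI profile (n = 20, iterations = 200,
#'   runs = 5)? Default `FALSE`.
#' @return An object of class `bench_suite`: a list with `summary` (one
#'   row per function x algorithm: `function_name`, `algorithm`, `best`,
#'   `mean`, `std`, `runs`) and `runs` (per-run best values and seeds).
#' @export
benchmark_suite <- function(functions = bench_names(),
                            algorithms = c("ngo", "ngo-lc"),
                            runs = 20L, n = 100L, iterations = 900L,
                            dimension = 30L, seed = 1L, fast = FALSE) {
  bad <- setdiff(algorithms, c("ngo", "ngo-lc"))
  if (length(bad) > 0L) {
    rlang::abort(paste0("Unknown algorithm(s): ", paste(bad, collapse = ", "),
                        ". Valid: ngo, ngo-lc."))
  }
  functions <- functions[order(match(functions, bench_names()))]
  if (fast) { n <- 20L; iterations <- 200L; runs <- 5L }
  grid <- tidyr::expand_grid(function_name = functions,
                             algorithm = algorithms,
                             run = seq_len(runs))
  run_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L,
                                           nrow(grid)))
  per_run <- purrr::pmap_dfr(
    list(grid$function_name, grid$algorithm, grid$run, run_seeds),
    function(fn, alg, run, s) {
      p <- bench_problem(fn, dimension)
      res <- ngo_optimize(p, ngo_config(n = n, iterations = iterations,
                                        seed = s, variant = alg))
      tibble::tibble(function_name = fn, algorithm = alg, run = run,
                     seed = s, best_value = res$best_value)
    })
  summary <- per_run |>
    dplyr::group_by(.data$function_name, .data$algorithm) |>
    dplyr::summarise(best = min(.data$best_value),
                     mean = mean(.data$best_value),
                     std = if (dplyr::n() > 1L) stats::sd(.data$best_value) else 0,
                     runs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$function_name, bench_names()),
                   .data$algorithm)
  structure(list(summary = summary, runs = per_run,
                 config = list(n = n, iterations = iterations,
                               dimension = dimension, seed = seed)),
            class = "bench_suite")
}

#' @export
print.bench_suite <- function(x, ...) {
  cat(sprintf("<bench_suite> %d run(s) per cell, n = %d, T = %d, d = %d\n",
              x$summary$runs[1L], x$config$n, x$config$iterations,
              x$config$dimension))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy a benchmark suite into its per-run results
#'
#' @param x A `bench_suite`.
#' @param ... Unused.
#' @return A tibble with one row per function x algorithm x run.
#' @method tidy bench_suite
#' @export
tidy.bench_suite <- function(x, ...) x$runs

#' Per-objective summary plot of a benchmark suite
#'
#' @param object A `bench_suite`.
#' @param ... Unused.
#' @return A ggplot of per-run best values by objective and algorithm
#'   (log10 y axis, values floored at 1e-300 for display).
#' @method autoplot bench_suite
#' @export
autoplot.bench_suite <- function(object, ...) {
  d <- object$runs
  d$best_value <- pmax(d$best_value, 1e-300)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$function_name,
                                  y = .data$best_value,
                                  color = .data$algorithm)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Best objective value per run",
                  color = "Algorithm") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write a benchmark suite summary as CSV
#'
#' Byte-identical across re-runs with the same suite.
#'
#' @param suite A `bench_suite`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(suite, path) {
  readr::write_csv(suite$summary, path)
  invisible(path)
}

#' Run the end-to-end classification experiment
#'
#' The full pipeline on a labeled image set: random oversampling of the
#' minority class, stratified 70/30 split, augmentation of the training
#' split only, standardizing resize, row-sequence encoding, GRU weight
#' training by the optimizer, and confusion-matrix metrics on the
#' held-out test split.
#'
#' @param data An image-set tibble (e.g. [synth_image_set()] or
#'   [read_image_tree()]).
#' @param size Standardized image side in pixels (default 32).
#' @param hidden_size GRU hidden size (default 8).
#' @param config An [ngo_config()] for the weight search.
#' @param train_fraction Train share of the split (default 0.7).
#' @param seed Master seed for oversampling, splitting and augmentation
#'   (the optimizer seed comes from `config`).
#' @param oversample,augment Toggle those stages.
#' @param aug_config An [augmentation_config()].
#' @return An object of class `oc_experiment`: the `fit` (a `gru_fit`),
#'   `metrics` (test-split metric tibble), `confusion`, `train_metrics`,
#'   `stage_counts` (images flowing through each stage), and the splits.
#' @export
classification_experiment <- function(data, size = 32L, hidden_size = 8L,
                                      config = ngo_config(n = 20L,
                                                          iterations = 200L,
                                                          seed = 1L),
                                      train_fraction = 0.7, seed = 1L,
                                      oversample = TRUE, augment = TRUE,
                                      aug_config = augmentation_config()) {
  stages <- list(input = nrow(data))
  if (oversample) {
    data <- ros_oversample(data, seed = seed)
    stages$oversampled <- nrow(data)
  }
  sp <- split_train_test(data, train_fraction, seed = seed + 1L)
  train <- sp$train; test <- sp$test
  stages$train <- nrow(train); stages$test <- nrow(test)
  if (augment) {
    train <- augment_images(train, aug_config, seed = seed + 2L)
    stages$train_augmented <- nrow(train)
  }
  train <- standardize_images(train, c(size, size))
  test <- standardize_images(test, c(size, size))
  enc_train <- encode_image_sequences(train)
  enc_test <- encode_image_sequences(test)
  fit <- gru_train(enc_train$x, enc_train$y,
                   spec = gru_spec(size, hidden_size), config = config)
  pred_test <- predict(fit, enc_test$x, type = "class")
  pred_train <- predict(fit, enc_train$x, type = "class")
  conf <- confusion_counts(pred_test, enc_test$y)
  structure(
    list(fit = fit,
         metrics = classification_metrics(conf),
         confusion = conf,
         train_metrics = classification_metrics(
           confusion_counts(pred_train, enc_train$y)),
         stage_counts = tibble::tibble(stage = names(stages),
                                       images = unname(unlist(stages))),
         train = train, test = test,
         settings = list(size = size, hidden_size = hidden_size,
                         train_fraction = train_fraction, seed = seed,
                         oversample = oversample, augment = augment)),
    class = "oc_experiment"
  )
}

#' @export
print.oc_experiment <- function(x, ...) {
  cat("<oc_experiment>\n")
  cat(sprintf("  train: %d images, test: %d images\n",
              nrow(x$train), nrow(x$test)))
  cat(sprintf("  train MSE %.4f, train accuracy %.3f\n",
              x$fit$train_fitness, x$fit$train_accuracy))
  m <- x$metrics
  cat("  test metrics:",
      paste(sprintf("%s %.2f", m$metric, m$value), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a classification experiment into its test metrics
#'
#' @param x An `oc_experiment`.
#' @param ... Unused.
#' @return The test-split metric tibble (`metric`, `value`).
#' @method tidy oc_experiment
#' @export
tidy.oc_experiment <- function(x, ...) x$metrics

#' One-row summary of a classification experiment
#'
#' @param x An `oc_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with test accuracy, train accuracy/fitness
#'   and sample counts.
#' @method glance oc_experiment
#' @export
glance.oc_experiment <- function(x, ...) {
  acc <- x$metrics$value[x$metrics$metric == "Accuracy"]
  tibble::tibble(
    test_accuracy = acc, train_accuracy = x$fit$train_accuracy,
    train_fitness = x$fit$train_fitness,
    n_train = nrow(x$train), n_test = nrow(x$test)
  )
}

#' Bar plot of a classification experiment's test metrics
#'
#' @param object An `oc_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oc_experiment
#' @export
autoplot.oc_experiment <- function(object, ...) {
  d <- object$metrics
  d$metric <- factor(d$metric, levels = d$metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "Value (0-100)") +
    ggplot2::coord_cartesian(ylim = c(0, 100))
}

#' Write a classification report as CSV and JSON
#'
#' Writes `metrics.csv` (test metrics), `confusion.csv` and
#' `report.json` under `dir`; outputs are byte-identical across re-runs
#' of the same experiment.
#'
#' @param x An `oc_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(x$confusion, file.path(dir, "confusion.csv"))
  jsonlite::write_json(
    list(metrics = x$metrics, confusion = x$confusion,
         train_metrics = x$train_metrics, stage_counts = x$stage_counts,
         train_fitness = x$fit$train_fitness,
         train_accuracy = x$fit$train_accuracy,
         settings = x$settings[c("size", "hidden_size", "train_fraction",
                                 "seed", "oversample", "augment")]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
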