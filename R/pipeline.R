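#' Read a records table from CSV
#'
#' Header row required. Columns are typed by inference: numeric when every
#' non-missing entry parses as a number, otherwise nominal (character). A
#' type census is attached as the `types` attribute.
#'
#' @param path CSV path.
#' @param outcome Outcome column name (must be present).
#' @param missing_token Text representing a missing cell.
#' @return Records tibble.
#' @export
read_feature_table <- function(path, outcome = "outcome",
                               missing_token = "") {
  if (!file.exists(path)) abort(sprintf("input file '%s' does not exist.", path))
  data <- readr::read_csv(path, na = missing_token, show_col_types = FALSE,
                          progress = FALSE)
  if (!outcome %in% names(data))
    abort(sprintf("outcome column '%s' is missing from '%s'.", outcome, path))
  types <- vapply(data, function(x)
    if (is.numeric(x)) "numeric" else "nominal", character(1))
  attr(data, "types") <- types[setdiff(names(types), outcome)]
  data
}

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end run. `data` may be a records tibble,
#' a [cohort_config()] (the cohort is generated), or a CSV path.
#'
#' @param data Input data (tibble, `cohort_config`, or path).
#' @param outcome Outcome column name.
#' @param missing_threshold,low_out,high_in Preprocessing thresholds.
#' @param tau_factor Network distance-threshold multiplier.
#' @param families,grids Stacked-ensemble layer families and grids.
#' @param k Cross-validation folds.
#' @param repetitions Experiment repetitions.
#' @param feature_mode `"original"`, `"engineered"`, `"both"` or `"topk"`.
#' @param top_k Number of features kept in `"topk"` mode.
#' @param validation_fraction,q_max Stacking options.
#' @param seed Integer seed.
#' @param output_dir Optional directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(data, outcome = "outcome", missing_threshold = 0.2,
                       low_out = 0.01, high_in = 0.95, tau_factor = 0.7,
                       families = c("logistic", "tree", "random_forest",
                                    "gbt"),
                       grids = learner_default_grid(), k = 5,
                       repetitions = 1,
                       feature_mode = c("engineered", "original", "both",
                                        "topk"),
                       top_k = 20, validation_fraction = 0.2, q_max = 0.9,
                       seed = 1L, output_dir = NULL) {
  feature_mode <- match.arg(feature_mode)
  if (missing_threshold < 0 || missing_threshold >= 1)
    abort("`missing_threshold` must lie in [0, 1).")
  if (tau_factor <= 0) abort("`tau_factor` must be positive.")
  if (k < 2) abort("`k` must be at least 2.")
  if (repetitions < 1) abort("`repetitions` must be at least 1.")
  structure(list(data = data, outcome = outcome,
                 missing_threshold = missing_threshold, low_out = low_out,
                 high_in = high_in, tau_factor = tau_factor,
                 families = families, grids = grids, k = k,
                 repetitions = repetitions, feature_mode = feature_mode,
                 top_k = top_k, validation_fraction = validation_fraction,
                 q_max = q_max, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

resolve_input <- function(config) {
  d <- config$data
  if (inherits(d, "cohort_config")) generate_cohort(d)
  else if (is.character(d)) read_feature_table(d, config$outcome)
  else as_tibble(d)
}

#' Run the end-to-end experiment
#'
#' Per repetition and fold: fit the preprocessing pipeline on the training
#' split, transform both splits, optionally engineer the 17 network-contrast
#' features (each training record leaving its own labelled copy out of its
#' networks), fit the stacked ensemble, and evaluate on the held-out fold.
#' Metrics are aggregated as mean +/- sd over all fold-repetition runs.
#'
#' @param config A [run_config()].
#' @return An object of class `psn_experiment` with `runs` (per-fold metric
#'   tibble), `summary` (mean +/- sd per metric), and the config.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- resolve_input(config)
  y_all <- as.integer(data[[config$outcome]])
  if (length(unique(y_all)) < 2) abort("the outcome has a single class.")
  runs <- list()
  for (rep_i in seq_len(config$repetitions)) {
    fold <- stratified_kfold(y_all, config$k,
                             seed = config$seed + 7919L * rep_i)
    for (f in seq_len(config$k)) {
      train_raw <- data[fold != f, , drop = FALSE]
      test_raw <- data[fold == f, , drop = FALSE]
      prep <- fit_preprocess(train_raw, config$outcome,
                             config$missing_threshold,
                             config$low_out, config$high_in)
      train_p <- prep$data
      test_p <- predict(prep, test_raw)
      sets <- assemble_feature_sets(train_p, test_p, config,
                                    seed = config$seed + rep_i)
      model <- fit_stacked(sets$x_train, sets$y_train,
                           families = config$families, grids = config$grids,
                           validation_fraction = config$validation_fraction,
                           q_max = config$q_max,
                           seed = config$seed + 104729L * rep_i + f)
      scores <- predict_score(model, sets$x_test)
      labels <- as.integer(scores >= 0.5)
      rep_metrics <- glance(confusion_metrics(sets$y_test, labels))
      runs[[length(runs) + 1]] <- dplyr::bind_cols(
        tibble(repetition = rep_i, fold = f),
        rep_metrics, tibble(auc = roc_auc(sets$y_test, scores)))
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs %>%
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity",
                          "f_score", "auc"),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  out <- structure(list(runs = runs, summary = summary, config = config),
                   class = "psn_experiment")
  if (!is.null(config$output_dir)) write_outputs(out, config$output_dir)
  out
}

# build train/test design matrices for the configured feature mode
assemble_feature_sets <- function(train_p, test_p, config, seed) {
  outcome <- config$outcome
  id_cols <- c("couple_id", "cycle")
  feats <- setdiff(names(train_p), c(outcome, id_cols))
  y_train <- as.integer(train_p[[outcome]])
  y_test <- as.integer(test_p[[outcome]])
  mode <- config$feature_mode
  if (mode == "topk") {
    rk <- mda_ranking(pipeline_logistic(), train_p, outcome,
                      repetitions = 1, folds = 3, seed = seed)
    feats <- utils::head(rk$ranking$feature, config$top_k)
    train_p <- train_p[c(id_cols[id_cols %in% names(train_p)], feats, outcome)]
    test_p <- test_p[c(id_cols[id_cols %in% names(test_p)], feats, outcome)]
    mode <- "original"
  }
  if (mode == "original")
    return(list(x_train = train_p[feats], x_test = test_p[feats],
                y_train = y_train, y_test = y_test))
  eng_train <- engineer_table(train_p, train_p, outcome,
                              config$tau_factor, self = TRUE)
  eng_test <- engineer_table(test_p, train_p, outcome, config$tau_factor)
  if (mode == "engineered")
    return(list(x_train = eng_train, x_test = eng_test,
                y_train = y_train, y_test = y_test))
  list(x_train = dplyr::bind_cols(train_p[feats], eng_train),
       x_test = dplyr::bind_cols(test_p[feats], eng_test),
       y_train = y_train, y_test = y_test)
}

#' @export
print.psn_experiment <- function(x, ...) {
  cat(sprintf("Experiment: %d repetition(s) x %d folds, feature mode '%s'\n",
              x$config$repetitions, x$config$k, x$config$feature_mode))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.psn_experiment <- function(x, ...) x$runs

#' @export
glance.psn_experiment <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Write experiment artifacts and a reproduction manifest
#'
#' @param experiment A `psn_experiment`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(experiment$runs, file.path(dir, "runs.tsv"))
  readr::write_tsv(experiment$summary, file.path(dir, "summary.tsv"))
  cfg <- experiment$config
  manifest <- list(
    outcome = cfg$outcome, missing_threshold = cfg$missing_threshold,
    low_out = cfg$low_out, high_in = cfg$high_in,
    tau_factor = cfg$tau_factor, families = cfg$families, k = cfg$k,
    repetitions = cfg$repetitions, feature_mode = cfg$feature_mode,
    top_k = cfg$top_k, validation_fraction = cfg$validation_fraction,
    q_max = cfg$q_max, seed = cfg$seed,
    input = if (is.character(cfg$data)) cfg$data else "in-memory")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
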