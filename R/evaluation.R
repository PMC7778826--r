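#' Confusion counts and classification metrics
#'
#' Accuracy = (TP + TN) / N, sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), and the F-score used throughout this package is the
#' harmonic mean of sensitivity and specificity,
#' 2 sens spec / (sens + spec) — *not* the precision/recall F1. An undefined
#' ratio (empty class) returns 0 with a warning.
#'
#' @param y_true,y_pred 0/1 label vectors of equal length.
#' @return An object of class `evaluation_report` (a list of counts and
#'   metrics); [tidy()] turns it into a tibble.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    abort("`y_true` and `y_pred` must have equal length.")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  n <- length(y_true)
  rate <- function(num, den) {
    if (den == 0) { warn("undefined ratio (empty class); returning 0."); 0 }
    else num / den
  }
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  fsc <- if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, N = n,
                 accuracy = (tp + tn) / n, sensitivity = sens,
                 specificity = spec, f_score = fsc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "TP %d  TN %d  FP %d  FN %d (N = %d)\naccuracy %.4f  sensitivity %.4f  specificity %.4f  F-score %.4f\n",
    x$TP, x$TN, x$FP, x$FN, x$N,
    x$accuracy, x$sensitivity, x$specificity, x$f_score))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity", "f_score"),
         value = c(x$accuracy, x$sensitivity, x$specificity, x$f_score))
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN, N = x$N,
         accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, f_score = x$f_score)
}

#' Area under the ROC curve
#'
#' Computed by the rank-sum (concordance) formulation: the probability that
#' a random positive scores above a random negative, with score ties
#' counting one half.
#'
#' @param y_true 0/1 labels.
#' @param scores Positive-class scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0) abort("both classes must be present.")
  r <- rank(scores)  # midranks handle ties
  (sum(r[y_true == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' One (false-positive rate, true-positive rate) point per distinct score
#' threshold, ordered from the strictest threshold down.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, of class `psn_roc`.
#' @export
roc_curve <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0) abort("both classes must be present.")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map(th, function(t) {
    pred <- scores >= t
    tibble(threshold = t, fpr = sum(pred & y_true == 0) / nneg,
           tpr = sum(pred & y_true == 1) / npos)
  })
  out <- dplyr::bind_rows(pts)
  class(out) <- c("psn_roc", class(out))
  out
}

#' Precision-recall curve points
#'
#' One (precision, recall) point per distinct score threshold, ordered from
#' the strictest threshold down, so recall is non-decreasing along the
#' table. The loosest threshold yields recall 1 and precision equal to the
#' prevalence.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `precision`, `recall`, of class
#'   `psn_pr`.
#' @export
precision_recall_curve <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1)
  if (npos == 0 || npos == length(y_true))
    abort("both classes must be present.")
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map(th, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           precision = if (any(pred)) sum(pred & y_true == 1) / sum(pred)
                       else 1,
           recall = sum(pred & y_true == 1) / npos)
  })
  out <- dplyr::bind_rows(pts)
  class(out) <- c("psn_pr", class(out))
  out
}

# ---- pipelines -------------------------------------------------------------
# A "pipeline" is any function(x_train, y_train) returning a function
# (x_new) -> 0/1 labels: the trainable unit resampled by a_test() and
# mda_ranking(). pipeline_stacked() adapts the full stacked ensemble;
# pipeline_logistic() is a fast plain-GLM unit for desk-scale ranking runs.

#' Trainable pipeline adaptors
#'
#' [a_test()] and [mda_ranking()] retrain a classifier many times; they
#' accept any function `(x_train, y_train) -> (x_new -> 0/1 labels)`.
#' `pipeline_stacked()` wraps [fit_stacked()]; `pipeline_logistic()` wraps a
#' plain logistic fit (fast, handy for feature-ranking runs);
#' `pipeline_learner()` wraps a single [base_learner()] family.
#'
#' @param ... Passed on to [fit_stacked()].
#' @return A pipeline function.
#' @export
pipeline_stacked <- function(...) {
  function(x, y) {
    model <- fit_stacked(x, y, ...)
    function(newx) predict(model, newx)
  }
}

#' @rdname pipeline_stacked
#' @export
pipeline_logistic <- function() {
  function(x, y) {
    fit <- learner_fit(base_learner("logistic"), x, y)
    function(newx) learner_predict(fit, newx)
  }
}

#' @rdname pipeline_stacked
#' @param family,params,seed Single-learner family specification.
#' @export
pipeline_learner <- function(family, params = list(), seed = 1L) {
  function(x, y) {
    fit <- learner_fit(base_learner(family, params), x, y, seed = seed)
    function(newx) learner_predict(fit, newx)
  }
}

#' A-Test structural risk
#'
#' For each K = 2..`k_max`, records are dealt into K stratified folds, each
#' fold is class-balanced by seeded minority oversampling within the fold,
#' the pipeline is trained on K-1 balanced folds and its misclassification
#' percentage on the held-out balanced fold is averaged over the K rotations,
#' giving the per-K error Gamma_K in [0, 100]. The structural-risk summary
#' Gamma_hat is the mean of Gamma_K over K. Low values indicate a stable,
#' generalising classifier; a label-independent classifier concentrates at
#' 50 on balanced folds.
#'
#' @param pipeline A trainable pipeline, see [pipeline_stacked()].
#' @param data Records tibble.
#' @param outcome Outcome column name.
#' @param k_max Largest K (at most the minority-class count).
#' @param seed Integer seed.
#' @param id_cols Identifier columns excluded from the features.
#' @return An object of class `atest_result` with `gamma_k` (tibble K,
#'   gamma) and `gamma_hat`.
#' @export
a_test <- function(pipeline, data, outcome = "outcome", k_max = 5, seed = 1L,
                   id_cols = c("couple_id", "cycle")) {
  y <- as.integer(data[[outcome]])
  n_min <- min(table(y))
  if (k_max < 2) abort("`k_max` must be at least 2.")
  if (k_max > n_min) abort("`k_max` exceeds the minority-class size.")
  feats <- setdiff(names(data), c(outcome, id_cols))
  x <- data[feats]
  gamma_k <- vapply(2:k_max, function(k) {
    fold <- stratified_kfold(y, k, seed = seed + k)
    errs <- vapply(seq_len(k), function(f) {
      balance <- function(idx, s) {
        d <- dplyr::bind_cols(x[idx, , drop = FALSE], tibble(.y = y[idx]))
        oversample_minority(d, ".y", seed = s)
      }
      tr <- balance(which(fold != f), seed + 100L * k + f)
      te <- balance(which(fold == f), seed + 200L * k + f)
      predictor <- pipeline(tr[feats], tr$.y)
      mean(predictor(te[feats]) != te$.y) * 100
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  structure(list(gamma_k = tibble(K = 2:k_max, gamma = gamma_k),
                 gamma_hat = mean(gamma_k), k_max = k_max, seed = seed),
            class = "atest_result")
}

#' @export
print.atest_result <- function(x, ...) {
  cat(sprintf("A-Test structural risk: Gamma_hat = %.2f (K = 2..%d)\n",
              x$gamma_hat, x$k_max))
  invisible(x)
}

#' @export
tidy.atest_result <- function(x, ...) x$gamma_k

#' @export
glance.atest_result <- function(x, ...) {
  tibble(gamma_hat = x$gamma_hat, gamma_min = min(x$gamma_k$gamma),
         k_max = x$k_max)
}

#' Leave-one-feature-out mean decrease in accuracy
#'
#' Per repetition, the baseline cross-validated accuracy of the pipeline is
#' measured on held-out validation folds; then each feature in turn is
#' removed and the pipeline retrained, and the accuracy drop is recorded in
#' percentage points. Drops are averaged over repetitions (each with its own
#' seed) and ranked in decreasing order — larger values mean more predictive
#' features; irrelevant features centre at 0.
#'
#' @param pipeline A trainable pipeline, see [pipeline_stacked()].
#' @param data Records tibble.
#' @param outcome Outcome column name.
#' @param repetitions Number of repetitions.
#' @param folds Cross-validation folds per repetition.
#' @param seed Integer seed.
#' @param id_cols Identifier columns excluded from the features.
#' @return An object of class `mda_ranking`; its `ranking` tibble has
#'   `feature`, `mda` (percentage points), `sd`, `rank`.
#' @export
mda_ranking <- function(pipeline, data, outcome = "outcome",
                        repetitions = 10, folds = 5, seed = 1L,
                        id_cols = c("couple_id", "cycle")) {
  feats <- setdiff(names(data), c(outcome, id_cols))
  if (length(feats) < 2) abort("at least two features are required.")
  if (repetitions < 1) abort("`repetitions` must be at least 1.")
  y <- as.integer(data[[outcome]])
  x <- data[feats]
  cv_accuracy <- function(cols, fold) {
    mean(vapply(seq_len(max(fold)), function(f) {
      tr <- fold != f
      predictor <- pipeline(x[tr, cols, drop = FALSE], y[tr])
      mean(predictor(x[!tr, cols, drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }
  drops <- matrix(NA_real_, repetitions, length(feats),
                  dimnames = list(NULL, feats))
  for (r in seq_len(repetitions)) {
    fold <- stratified_kfold(y, folds, seed = seed + 1000L * r)
    base_acc <- cv_accuracy(feats, fold)
    for (j in seq_along(feats))
      drops[r, j] <- (base_acc - cv_accuracy(feats[-j], fold)) * 100
  }
  ranking <- tibble(feature = feats,
                    mda = colMeans(drops),
                    sd = apply(drops, 2, sd)) %>%
    arrange(desc(.data$mda)) %>%
    mutate(rank = dplyr::row_number())
  structure(list(ranking = ranking, repetitions = repetitions,
                 folds = folds, seed = seed, drops = drops),
            class = "mda_ranking")
}

#' @export
print.mda_ranking <- function(x, ...) {
  cat(sprintf("MDA feature ranking over %d repetition(s):\n", x$repetitions))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' @export
tidy.mda_ranking <- function(x, ...) x$ranking

#' Partial dependence of the model score on one feature
#'
#' For each grid value the feature is set to that value on every record and
#' the mean model score is recorded, tracing the feature's marginal effect
#' while the remaining features stay at their observed values.
#'
#' @param model A fitted `stacked_model`, or any function mapping a feature
#'   data frame to scores.
#' @param data Records tibble (features only are used).
#' @param feature Feature name to sweep.
#' @param grid Numeric grid of values (default: 21 quantile-spanning
#'   points).
#' @param outcome,id_cols Columns excluded from the model input.
#' @return Tibble with `value` and `score`, of class `psn_pdp`.
#' @export
partial_dependence <- function(model, data, feature, grid = NULL,
                               outcome = "outcome",
                               id_cols = c("couple_id", "cycle")) {
  feats <- setdiff(names(data), c(outcome, id_cols))
  if (!feature %in% feats) abort(sprintf("feature '%s' not found.", feature))
  x <- data[feats]
  if (is.null(grid))
    grid <- unname(quantile(x[[feature]], probs = seq(0, 1, length.out = 21)))
  if (!length(grid)) abort("empty grid.")
  scorer <- if (is.function(model)) model
            else function(xx) predict_score(model, xx)
  out <- tibble(value = grid,
                score = vapply(grid, function(v) {
                  xx <- x
                  xx[[feature]] <- v
                  mean(scorer(xx))
                }, numeric(1)))
  attr(out, "feature") <- feature
  class(out) <- c("psn_pdp", class(out))
  out
}

#' Write evaluation artifacts to disk
#'
#' @param report An `evaluation_report` (JSON) or curve/ranking tibble
#'   (TSV).
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_tsv_artifact <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
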