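#' Yule's Q statistic between two classifiers
#'
#' Measures the association of two classifiers' correctness patterns on the
#' same records: with N11 = both correct, N00 = both wrong and N01/N10 =
#' exactly one correct, Q = (N11 N00 - N01 N10) / (N11 N00 + N01 N10).
#' Values near +/-1 indicate low diversity. When the denominator is zero the
#' convention is Q = 1 for identical correctness patterns and 0 otherwise.
#'
#' @param pred_a,pred_b Label vectors of two classifiers.
#' @param truth True label vector.
#' @return Q in [-1, 1].
#' @export
q_statistic <- function(pred_a, pred_b, truth) {
  if (length(pred_a) != length(pred_b) || length(pred_a) != length(truth))
    abort("prediction and truth vectors must have equal length.")
  ca <- pred_a == truth; cb <- pred_b == truth
  n11 <- sum(ca & cb); n00 <- sum(!ca & !cb)
  n01 <- sum(!ca & cb); n10 <- sum(ca & !cb)
  den <- n11 * n00 + n01 * n10
  if (den == 0) return(if (all(ca == cb)) 1 else 0)
  (n11 * n00 - n01 * n10) / den
}

#' Select ensemble members by accuracy and diversity
#'
#' Ranks fitted candidates by validation accuracy and admits them greedily,
#' rejecting a candidate whose absolute Q statistic with any already-admitted
#' learner exceeds `q_max`. The most accurate candidate is always admitted.
#'
#' @param candidates List of fitted [base_learner()]s.
#' @param x_val,y_val Validation features and labels.
#' @param q_max Diversity threshold in [0, 1].
#' @return The admitted sub-list, in accuracy order, with attributes
#'   `accuracy` and `selection` (a tibble logging every decision).
#' @export
select_learners <- function(candidates, x_val, y_val, q_max = 0.9) {
  if (!length(candidates)) abort("empty candidate set.")
  preds <- lapply(candidates, learner_predict, x = x_val)
  acc <- vapply(preds, function(p) mean(p == y_val), numeric(1))
  ord <- order(acc, decreasing = TRUE)
  admitted <- integer(0)
  log <- list()
  for (i in ord) {
    qs <- vapply(admitted, function(j)
      abs(q_statistic(preds[[i]], preds[[j]], y_val)), numeric(1))
    ok <- !length(admitted) || all(qs <= q_max)
    if (ok) admitted <- c(admitted, i)
    log[[length(log) + 1]] <-
      tibble(id = candidates[[i]]$id, accuracy = acc[i],
             max_abs_q = if (length(qs)) max(qs) else NA_real_,
             admitted = ok)
  }
  out <- candidates[admitted]
  attr(out, "accuracy") <- acc[admitted]
  attr(out, "selection") <- dplyr::bind_rows(log)
  out
}

#' Exhaustive grid search over learner hyperparameters
#'
#' Fits every grid cell on the training split and returns the cell with the
#' highest validation accuracy; ties resolve to the earlier cell in grid
#' order.
#'
#' @param family Learner family, see [base_learner()].
#' @param grid List of hyperparameter maps.
#' @param x_train,y_train Training split.
#' @param x_val,y_val Validation split.
#' @param seed Integer seed.
#' @return List with `params`, `accuracy`, the fitted `learner`, and the
#'   per-cell `results` tibble.
#' @export
tune_hyperparameters <- function(family, grid, x_train, y_train,
                                 x_val, y_val, seed = 1L) {
  if (!length(grid)) abort("empty hyperparameter grid.")
  fits <- vector("list", length(grid))
  acc <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- learner_fit(base_learner(family, grid[[i]]),
                             x_train, y_train, seed = seed)
    acc[i] <- mean(learner_predict(fits[[i]], x_val) == y_val)
  }
  best <- which.max(acc)  # first max wins ties
  list(params = grid[[best]], accuracy = acc[best], learner = fits[[best]],
       results = tibble(cell = seq_along(grid), accuracy = acc))
}

#' Validation-accuracy-weighted vote
#'
#' Aggregates per-learner positive-class scores as the weighted mean
#' `sum(w * s) / sum(w)`; the label is positive when the aggregate reaches
#' 0.5 (an exact 0.5 counts as positive).
#'
#' @param scores Per-learner scores for one record.
#' @param weights Per-learner vote weights (validation accuracies).
#' @return List with `label` (0/1) and `score` (the aggregate).
#' @export
weighted_vote <- function(scores, weights) {
  if (length(scores) != length(weights))
    abort("`scores` and `weights` must have equal length.")
  if (sum(weights) <= 0) abort("vote weights must sum to a positive value.")
  s <- sum(weights * scores) / sum(weights)
  list(label = as.integer(s >= 0.5), score = s)
}

#' Fit the two-layer stacked ensemble
#'
#' Implements normal-mode stacking: (1) a stratified `validation_fraction`
#' of the data is held out; (2) the remainder is class-balanced by minority
#' oversampling; (3) one candidate per requested family is tuned by grid
#' search and fitted, and the layer-1 members are selected by validation
#' accuracy and Q-statistic diversity; (4) the admitted layer-1 scores form
#' the meta-feature matrix; (5) layer-2 learners are fitted on meta-features
#' only and selected the same way; (6) each admitted layer-2 learner's
#' validation accuracy becomes its vote weight for the final
#' weighted-voting aggregation.
#'
#' @param x Numeric feature data frame.
#' @param y 0/1 outcome vector.
#' @param families Families for both layers (default: all six), or a list
#'   with elements `layer1` and `layer2`.
#' @param grids Named list of hyperparameter grids
#'   (default [learner_default_grid()]).
#' @param validation_fraction Held-out share used for tuning, selection and
#'   vote weights.
#' @param q_max Diversity admission threshold.
#' @param meta `"score"` (default) to pass layer-1 positive-class scores as
#'   meta-features, `"label"` for hard 0/1 meta-features.
#' @param seed Integer seed; identical inputs and seeds refit identically.
#' @return An object of class `stacked_model`.
#' @export
fit_stacked <- function(x, y,
                        families = c("logistic", "svm", "tree",
                                     "random_forest", "adaboost", "gbt"),
                        grids = learner_default_grid(),
                        validation_fraction = 0.2, q_max = 0.9,
                        meta = c("score", "label"), seed = 1L) {
  meta <- match.arg(meta)
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("both classes must be present.")
  fam1 <- if (is.list(families)) families$layer1 else families
  fam2 <- if (is.list(families)) families$layer2 else families

  # stratified validation hold-out
  set.seed(seed)
  val_idx <- unlist(lapply(unique(y), function(cls) {
    idx <- which(y == cls)
    n_val <- round(validation_fraction * length(idx))
    if (n_val >= length(idx)) abort("validation split would empty a class.")
    sample(idx, n_val)
  }))
  if (length(unique(y[val_idx])) < 2 || length(unique(y[-val_idx])) < 2)
    abort("validation split would empty a class.")
  x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  train <- dplyr::bind_cols(as_tibble(x[-val_idx, , drop = FALSE]),
                            tibble(.y = y[-val_idx]))
  train_bal <- oversample_minority(train, outcome = ".y", seed = seed + 1L)
  x_tr <- train_bal[setdiff(names(train_bal), ".y")]
  y_tr <- train_bal$.y

  tune1 <- lapply(seq_along(fam1), function(i)
    tune_hyperparameters(fam1[i], grids[[fam1[i]]], x_tr, y_tr,
                         x_val, y_val, seed = seed + 10L + i))
  cand1 <- lapply(tune1, `[[`, "learner")
  layer1 <- select_learners(cand1, x_val, y_val, q_max)

  meta_of <- function(xx) {
    m <- vapply(layer1, function(l) {
      s <- learner_score(l, xx)
      if (meta == "label") as.numeric(s >= 0.5) else s
    }, numeric(nrow(xx)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(xx))
    colnames(m) <- paste0("meta_", seq_along(layer1))
    as.data.frame(m)
  }
  meta_tr <- meta_of(x_tr)
  meta_val <- meta_of(x_val)

  tune2 <- lapply(seq_along(fam2), function(i)
    tune_hyperparameters(fam2[i], grids[[fam2[i]]], meta_tr, y_tr,
                         meta_val, y_val, seed = seed + 100L + i))
  cand2 <- lapply(tune2, `[[`, "learner")
  layer2 <- select_learners(cand2, meta_val, y_val, q_max)
  vote_weights <- attr(layer2, "accuracy")

  structure(
    list(layer1 = layer1, layer2 = layer2, vote_weights = vote_weights,
         meta = meta, validation_fraction = validation_fraction,
         q_max = q_max, seed = seed,
         feature_names = colnames(x),
         selection = list(layer1 = attr(layer1, "selection"),
                          layer2 = attr(layer2, "selection")),
         layer1_val_accuracy = attr(layer1, "accuracy")),
    class = "stacked_model")
}

# layer-1 meta-feature matrix for new data
stacked_meta <- function(model, x) {
  m <- vapply(model$layer1, function(l) {
    s <- learner_score(l, x)
    if (model$meta == "label") as.numeric(s >= 0.5) else s
  }, numeric(nrow(x)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(x))
  colnames(m) <- paste0("meta_", seq_along(model$layer1))
  as.data.frame(m)
}

#' Predict with a stacked ensemble
#'
#' Scores flow through layer 1 into the meta-feature map, through the
#' layer-2 learners, and are aggregated by validation-accuracy-weighted
#' voting; labels threshold the aggregate at 0.5.
#'
#' @param object A fitted `stacked_model`.
#' @param x New feature data with the training columns.
#' @param ... Unused.
#' @return For `predict_score`, aggregate scores in [0, 1]; for `predict`,
#'   0/1 labels.
#' @export
predict_score <- function(object, x, ...) UseMethod("predict_score")

#' @rdname predict_score
#' @export
predict_score.stacked_model <- function(object, x, ...) {
  x <- as.data.frame(x)
  if (!all(object$feature_names %in% colnames(x)))
    abort("`x` lacks some training feature columns.")
  x <- x[object$feature_names]
  mm <- stacked_meta(object, x)
  s2 <- vapply(object$layer2, learner_score, numeric(nrow(mm)), x = mm)
  if (is.null(dim(s2))) s2 <- matrix(s2, nrow = nrow(mm))
  w <- object$vote_weights
  if (sum(w) <= 0) abort("vote weights must sum to a positive value.")
  as.numeric(s2 %*% w) / sum(w)
}

#' @rdname predict_score
#' @export
predict.stacked_model <- function(object, x, ...) {
  as.integer(predict_score(object, x) >= 0.5)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf(
    "Two-layer stacked ensemble: %d layer-1 + %d layer-2 learners (meta = %s)\n",
    length(x$layer1), length(x$layer2), x$meta))
  cat("  layer 1:", paste(vapply(x$layer1, `[[`, "", "id"), collapse = ", "),
      "\n  layer 2:", paste(vapply(x$layer2, `[[`, "", "id"), collapse = ", "),
      "\n  vote weights:", paste(sprintf("%.3f", x$vote_weights),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.stacked_model <- function(x, ...) {
  dplyr::bind_rows(
    x$selection$layer1 %>% mutate(layer = 1L, .before = 1),
    x$selection$layer2 %>% mutate(layer = 2L, .before = 1))
}

#' @export
glance.stacked_model <- function(x, ...) {
  tibble(n_layer1 = length(x$layer1), n_layer2 = length(x$layer2),
         meta = x$meta, validation_fraction = x$validation_fraction,
         q_max = x$q_max,
         mean_vote_weight = mean(x$vote_weights), seed = x$seed)
}

# ---- analytic ensemble error rates ----------------------------------------

#' Majority-vote error of independent voters
#'
#' The probability that a majority of `m` independent classifiers, each
#' erring with probability `eps`, misclassify a record: the binomial upper
#' tail P(X >= (m+1)/2) with X ~ Binomial(m, eps), summed termwise.
#'
#' @param m Odd number of voters.
#' @param eps Per-voter error rate in [0, 1].
#' @return Ensemble error rate.
#' @export
majority_vote_error <- function(m, eps) {
  if (m < 1 || m %% 2 == 0) abort("`m` must be a positive odd count.")
  if (eps < 0 || eps > 1) abort("`eps` must lie in [0, 1].")
  k <- seq((m + 1) / 2, m)
  sum(dbinom(k, m, eps))
}

#' Layer error rates of a two-layer stacked ensemble
#'
#' Computes the second-layer error `eps_L2 = majority_vote_error(m2,
#' eps_b2)` together with the bound `majority_vote_error(m2, eps_L1)`, where
#' `eps_L1 = majority_vote_error(m, eps)` is the first-layer (bagging)
#' error. Under the premise `eps_b2 <= eps_L1` the bound dominates, giving
#' the ordering eps_L2 <= eps_L1 <= eps for eps < 0.5.
#'
#' @param m,eps Layer-1 voter count (odd) and per-voter error.
#' @param m2 Layer-2 voter count (odd).
#' @param eps_b2 Per-voter error of layer-2 members (defaults to the layer-1
#'   ensemble error, the analysis' worst case).
#' @return Tibble with `eps`, `eps_L1`, `eps_b2`, `eps_L2`, `bound`.
#' @export
stacked_error_bound <- function(m, eps, m2, eps_b2 = NULL) {
  eps_l1 <- majority_vote_error(m, eps)
  if (is.null(eps_b2)) eps_b2 <- eps_l1
  if (eps_b2 > eps_l1)
    warn("premise eps_b2 <= eps_L1 violated; both values returned anyway.")
  eps_l2 <- majority_vote_error(m2, eps_b2)
  bound <- majority_vote_error(m2, eps_l1)
  tibble(eps = eps, eps_L1 = eps_l1, eps_b2 = eps_b2,
         eps_L2 = eps_l2, bound = bound)
}
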