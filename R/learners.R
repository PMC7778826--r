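#' Construct a base learner specification
#'
#' A base learner is one of six families with a family-specific
#' hyperparameter map. Each fitted learner exposes a positive-class score in
#' [0, 1] via [learner_score()] and hard labels via [learner_predict()]
#' (score thresholded at 0.5).
#'
#' Families: `"logistic"` (GLM), `"svm"` (e1071, probability outputs),
#' `"tree"` (rpart), `"random_forest"` (ranger probability forest),
#' `"adaboost"` (AdaBoost.M1 over rpart stumps, implemented in-package),
#' `"gbt"` (xgboost, binary logistic objective).
#'
#' @param family Learner family.
#' @param params Named list of hyperparameters (defaults per family are
#'   documented in [learner_default_grid()]).
#' @param id Optional label used in reports.
#' @return An object of class `base_learner`.
#' @export
base_learner <- function(family = c("logistic", "svm", "tree",
                                    "random_forest", "adaboost", "gbt"),
                         params = list(), id = NULL) {
  family <- match.arg(family)
  structure(list(family = family, params = params,
                 id = id %||% family, fitted = NULL),
            class = "base_learner")
}

#' Default hyperparameter grids per learner family
#'
#' Small documented lattices used by [tune_hyperparameters()] and
#' [fit_stacked()]. Each element is a list of candidate hyperparameter maps
#' evaluated exhaustively in order.
#'
#' @return Named list of grids.
#' @export
learner_default_grid <- function() {
  list(
    logistic = list(list()),
    svm = list(list(kernel = "radial", cost = 1),
               list(kernel = "radial", cost = 10)),
    tree = list(list(maxdepth = 4), list(maxdepth = 8)),
    random_forest = list(list(num_trees = 150)),
    adaboost = list(list(n_rounds = 40, maxdepth = 1)),
    gbt = list(list(nrounds = 40, max_depth = 3, eta = 0.3)))
}

#' Fit a base learner
#'
#' @param learner A [base_learner()].
#' @param x Numeric feature data frame / matrix.
#' @param y 0/1 outcome vector.
#' @param seed Integer seed (stochastic families are seeded, so refits
#'   reproduce).
#' @return The learner with `fitted` state populated.
#' @export
learner_fit <- function(learner, x, y, seed = 1L) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  set.seed(seed)
  if (learner$family == "custom") {
    learner$fitted <- learner$fit_fn(x, y)
    learner$feature_names <- colnames(x)
    return(learner)
  }
  if (length(unique(y)) < 2) abort("both classes are required to fit.")
  p <- learner$params
  fitted <- switch(
    learner$family,
    logistic = {
      df <- cbind(x, .y = y)
      suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    },
    svm = e1071::svm(x = as.matrix(x), y = factor(y, levels = 0:1),
                     kernel = p$kernel %||% "radial",
                     cost = p$cost %||% 1,
                     gamma = p$gamma %||% (1 / max(1, ncol(x))),
                     probability = TRUE, scale = FALSE),
    tree = {
      df <- cbind(x, .y = factor(y, levels = 0:1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = p$maxdepth %||% 8,
                     cp = p$cp %||% 0.001, xval = 0))
    },
    random_forest = {
      df <- cbind(x, .y = factor(y, levels = 0:1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     num.trees = p$num_trees %||% 150,
                     mtry = p$mtry, seed = seed, num.threads = 1)
    },
    adaboost = adaboost_fit(x, y, n_rounds = p$n_rounds %||% 40,
                            maxdepth = p$maxdepth %||% 1),
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = p$max_depth %||% 3,
                                       eta = p$eta %||% 0.3, nthread = 1),
                         data = dtrain, nrounds = p$nrounds %||% 40,
                         verbose = 0)
    })
  learner$fitted <- fitted
  learner$feature_names <- colnames(x)
  learner
}

#' Positive-class score of a fitted base learner
#' @param learner Fitted [base_learner()].
#' @param x New feature data.
#' @return Numeric scores in [0, 1].
#' @export
learner_score <- function(learner, x) {
  if (is.null(learner$fitted)) abort("learner is not fitted.")
  x <- as.data.frame(x)
  if (!is.null(learner$feature_names)) {
    if (!all(learner$feature_names %in% colnames(x)))
      abort("feature columns of `x` do not match the training columns.")
    x <- x[learner$feature_names]
  }
  f <- learner$fitted
  if (learner$family == "custom")
    return(pmin(1, pmax(0, as.numeric(learner$score_fn(f, x)))))
  s <- switch(
    learner$family,
    logistic = as.numeric(predict(f, newdata = x, type = "response")),
    svm = {
      pr <- predict(f, as.matrix(x), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    tree = predict(f, newdata = x, type = "prob")[, "1"],
    random_forest = predict(f, data = x, num.threads = 1)$predictions[, "1"],
    adaboost = adaboost_score(f, x),
    gbt = as.numeric(predict(f, xgboost::xgb.DMatrix(as.matrix(x),
                                                     nthread = 1))))
  pmin(1, pmax(0, as.numeric(s)))
}

#' @rdname learner_score
#' @return Hard 0/1 labels (`score >= 0.5` is positive).
#' @export
learner_predict <- function(learner, x) {
  as.integer(learner_score(learner, x) >= 0.5)
}

#' Plug in a learner outside the six built-in families
#'
#' Any classifier satisfying the fit/score contract can join an ensemble:
#' `fit(x, y)` returns an opaque state, `score(state, x)` returns
#' positive-class scores in [0, 1].
#'
#' @param fit Function `(x, y) -> state`.
#' @param score Function `(state, x) -> scores`.
#' @param id Label used in reports.
#' @return A `base_learner` of family `"custom"`.
#' @export
custom_learner <- function(fit, score, id = "custom") {
  structure(list(family = "custom", params = list(), id = id,
                 fit_fn = fit, score_fn = score, fitted = NULL),
            class = "base_learner")
}

# ---- AdaBoost.M1 over rpart stumps ----------------------------------------
# Classic reweighting boost: at round t fit a depth-limited tree under the
# current record weights, weigh it by alpha = 0.5 log((1-err)/err), and
# exponentially up-weight the misclassified records. The score maps the
# aggregated margin through a logistic link.
adaboost_fit <- function(x, y, n_rounds = 40, maxdepth = 1) {
  n <- nrow(x)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  df <- cbind(x, .y = factor(y, levels = 0:1))
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = -1, minsplit = 2,
                          xval = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err >= 0.5) break
    err <- max(err, 1e-12)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-10) break
  }
  if (!length(stumps)) {  # nothing beat chance: fall back to prior margin
    prior <- mean(y)
    return(structure(list(stumps = list(), alphas = numeric(0),
                          prior = prior), class = "psn_adaboost"))
  }
  structure(list(stumps = stumps, alphas = alphas, prior = mean(y)),
            class = "psn_adaboost")
}

adaboost_score <- function(model, x) {
  if (!length(model$stumps)) return(rep(model$prior, nrow(x)))
  M <- vapply(seq_along(model$stumps), function(t) {
    pred <- ifelse(predict(model$stumps[[t]], x, type = "class") == "1",
                   1, -1)
    model$alphas[t] * pred
  }, numeric(nrow(x)))
  if (is.null(dim(M))) M <- matrix(M, nrow = nrow(x))
  margins <- rowSums(M)
  plogis(2 * margins)
}
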