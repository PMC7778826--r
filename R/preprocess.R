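#' Drop features, then records, with too many missing values
#'
#' A feature (then a record) is removed when its missing fraction is
#' *strictly greater* than `threshold`; a column missing exactly the
#' threshold fraction is retained. Row order of the survivors is preserved.
#'
#' @param data Records tibble.
#' @param outcome Name of the outcome column (never dropped, must be
#'   complete).
#' @param threshold Maximum tolerated missing fraction, in [0, 1).
#' @param id_cols Columns exempt from the rule (identifiers).
#' @return Filtered tibble; attribute `report` lists dropped features and
#'   records with their missing rates.
#' @export
drop_high_missing <- function(data, outcome = "outcome", threshold = 0.2,
                              id_cols = c("couple_id", "cycle")) {
  if (threshold < 0 || threshold >= 1) abort("`threshold` must lie in [0, 1).")
  if (anyNA(data[[outcome]])) abort("missing outcomes are not allowed.")
  feats <- setdiff(names(data), c(outcome, id_cols))
  rate_f <- vapply(data[feats], function(x) mean(is.na(x)), numeric(1))
  drop_f <- names(rate_f)[rate_f > threshold]
  if (length(drop_f) == length(feats))
    abort(sprintf("all features exceed the %.0f%% missing threshold.",
                  100 * threshold))
  kept <- data[setdiff(names(data), drop_f)]
  kept_feats <- setdiff(feats, drop_f)
  rate_r <- rowMeans(is.na(kept[kept_feats]))
  drop_r <- which(rate_r > threshold)
  out <- if (length(drop_r)) kept[-drop_r, ] else kept
  attr(out, "report") <- list(
    dropped_features_missing = tibble(feature = drop_f,
                                      missing_rate = unname(rate_f[drop_f]),
                                      rule = "missing_rate"),
    dropped_records_missing = tibble(row = drop_r,
                                     missing_rate = unname(rate_r[drop_r])))
  out
}

#' Impute missing values with column mean / mode
#'
#' Numeric columns are filled with the mean of the observed values,
#' categorical columns with the most frequent observed level (ties broken by
#' the lexicographically smallest level).
#'
#' @param data Records tibble.
#' @param stats Optional fitted statistics (named list of fill values) from a
#'   previous call's `params` attribute; when supplied, those values are used
#'   instead of refitting, so held-out data is filled with training
#'   statistics.
#' @return Completed tibble; attribute `params` holds the fill values.
#' @export
impute_missing <- function(data, stats = NULL) {
  if (is.null(stats)) {
    stats <- lapply(data, function(x) {
      obs <- x[!is.na(x)]
      if (length(obs) == 0) return(NA)
      if (is.numeric(x)) mean(obs) else {
        tab <- table(obs)
        # ties: table() orders levels lexicographically, so the first max wins
        names(tab)[which.max(tab)]
      }
    })
  }
  for (nm in names(data)) {
    miss <- is.na(data[[nm]])
    if (!any(miss)) next
    fill <- stats[[nm]]
    if (is.null(fill) || (length(fill) == 1 && is.na(fill)))
      abort(sprintf("column '%s' is entirely missing; drop it first.", nm))
    data[[nm]][miss] <- fill
  }
  attr(data, "params") <- stats
  data
}

#' Dummy-code nominal features
#'
#' Every categorical feature with m observed levels becomes m - 1 binary
#' indicator columns named `<feature>..<level>`; the reference level (the
#' most frequent at fit time, ties to the lexicographically smallest) is
#' dropped, so a two-level feature becomes a single column. Levels unseen at
#' fit time encode as all-zero indicators with a warning.
#'
#' @param data Records tibble (categorical columns are character/factor).
#' @param outcome,id_cols Columns passed through untouched.
#' @param map Optional fitted encoding map (the `map` attribute of a previous
#'   call) to apply to new data.
#' @return Numeric tibble; attributes `map` (encoding map) and `report`.
#' @export
dummy_encode <- function(data, outcome = "outcome",
                         id_cols = c("couple_id", "cycle"), map = NULL) {
  pass <- intersect(c(outcome, id_cols), names(data))
  feats <- setdiff(names(data), pass)
  is_cat <- vapply(data[feats], function(x) is.character(x) || is.factor(x),
                   logical(1))
  if (is.null(map)) {
    map <- lapply(data[feats[is_cat]], function(x) {
      x <- as.character(x)
      tab <- table(x)
      ref <- names(tab)[which.max(tab)]
      list(levels = sort(names(tab)), reference = ref,
           encoded = setdiff(sort(names(tab)), ref))
    })
  }
  out <- list()
  for (nm in feats) {
    if (!nm %in% names(map)) {
      out[[nm]] <- data[[nm]]
      next
    }
    enc <- map[[nm]]
    x <- as.character(data[[nm]])
    unseen <- setdiff(unique(x), enc$levels)
    if (length(unseen))
      warn(sprintf("column '%s': unseen level(s) %s encoded as reference.",
                   nm, paste(unseen, collapse = ", ")))
    for (lev in enc$encoded)
      out[[paste0(nm, "..", lev)]] <- as.numeric(x == lev)
  }
  res <- dplyr::bind_cols(if (length(intersect(id_cols, names(data))))
                            data[intersect(id_cols, names(data))],
                          as_tibble(out),
                          data[intersect(outcome, names(data))])
  attr(res, "map") <- map
  attr(res, "report") <- list(encoding_map = map)
  res
}

#' Min-max scale numeric features to [0, 1]
#'
#' Columns are rescaled as (x - min) / (max - min) with the fit-time minimum
#' and maximum; transform-time values outside the fitted range clip to
#' [0, 1]. A constant column maps to all zeros.
#'
#' @param data Numeric records tibble.
#' @param outcome,id_cols Columns passed through untouched.
#' @param params Optional fitted min/max (the `params` attribute of a
#'   previous call).
#' @return Scaled tibble; attribute `params` holds per-feature min and max.
#' @export
minmax_normalize <- function(data, outcome = "outcome",
                             id_cols = c("couple_id", "cycle"),
                             params = NULL) {
  pass <- intersect(c(outcome, id_cols), names(data))
  feats <- setdiff(names(data), pass)
  if (!all(vapply(data[feats], is.numeric, logical(1))))
    abort("all feature columns must be numeric; dummy-encode first.")
  if (is.null(params))
    params <- lapply(data[feats],
                     function(x) list(min = min(x), max = max(x)))
  for (nm in intersect(feats, names(params))) {
    p <- params[[nm]]
    rng <- p$max - p$min
    data[[nm]] <- if (rng == 0) rep(0, nrow(data))
                  else pmin(1, pmax(0, (data[[nm]] - p$min) / rng))
  }
  attr(data, "params") <- params
  data
}

#' Pearson linear correlation coefficient
#'
#' The sample linear correlation between two equal-length vectors, computed
#' from its defining sum form. A constant vector makes the coefficient
#' undefined; 0 is returned with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1].
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need at least two observations.")
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dy^2))
  if (den == 0) {
    warn("correlation undefined for a constant vector; returning 0.")
    return(0)
  }
  sum(dx * dy) / den
}

#' Remove outcome-irrelevant and mutually redundant features
#'
#' First drops every feature whose absolute correlation with the outcome is
#' below `low_out`; then, scanning remaining feature pairs in column order,
#' whenever a pair's absolute mutual correlation exceeds `high_in` the member
#' with the smaller absolute outcome correlation is dropped (ties drop the
#' later column).
#'
#' @param data Fully numeric records tibble.
#' @param outcome Outcome column name.
#' @param low_out Minimum |corr with outcome| to keep a feature.
#' @param high_in Maximum tolerated |corr| between two kept features.
#' @param id_cols Identifier columns ignored by the filter.
#' @param keep Optional character vector of features to retain (the fitted
#'   selection from a previous call), applied instead of refitting.
#' @return Filtered tibble; attribute `report` logs each decision.
#' @export
filter_irrelevant <- function(data, outcome = "outcome", low_out = 0.01,
                              high_in = 0.95,
                              id_cols = c("couple_id", "cycle"),
                              keep = NULL) {
  pass <- intersect(c(id_cols, outcome), names(data))
  feats <- setdiff(names(data), pass)
  if (!is.null(keep)) {
    out <- data[c(intersect(id_cols, names(data)), keep,
                  intersect(outcome, names(data)))]
    attr(out, "keep") <- keep
    return(out)
  }
  if (low_out < 0 || low_out > 1 || high_in < 0 || high_in > 1)
    abort("thresholds must lie in [0, 1].")
  y <- as.numeric(data[[outcome]])
  r_out <- vapply(data[feats], function(x)
    suppressWarnings(abs(pearson_corr(as.numeric(x), y))), numeric(1))
  low_dropped <- names(r_out)[r_out < low_out]
  kept <- setdiff(feats, low_dropped)
  if (length(kept) == 0)
    abort("every feature fell below the outcome-correlation threshold.")
  redundant <- character(0)
  red_log <- list()
  if (length(kept) > 1 && high_in < 1) {
    cm <- suppressWarnings(stats::cor(as.matrix(data[kept])))
    cm[is.na(cm)] <- 0
    for (i in seq_len(length(kept) - 1)) {
      a <- kept[i]
      if (a %in% redundant) next
      for (j in seq(i + 1, length(kept))) {
        b <- kept[j]
        if (b %in% redundant) next
        if (abs(cm[a, b]) > high_in) {
          victim <- if (r_out[a] < r_out[b]) a else b  # tie: later column b
          redundant <- c(redundant, victim)
          red_log[[length(red_log) + 1]] <-
            tibble(feature = victim, partner = setdiff(c(a, b), victim),
                   correlation = cm[a, b])
          if (victim == a) break
        }
      }
    }
  }
  kept <- setdiff(kept, redundant)
  if (length(kept) == 0) abort("all features dropped by the pairwise filter.")
  out <- data[c(intersect(id_cols, names(data)), kept,
                intersect(outcome, names(data)))]
  attr(out, "keep") <- kept
  attr(out, "report") <- list(
    dropped_features_correlation = dplyr::bind_rows(
      tibble(feature = low_dropped, partner = NA_character_,
             correlation = unname(r_out[low_dropped])),
      if (length(red_log)) dplyr::bind_rows(red_log)))
  out
}

#' Stratified K-fold assignment
#'
#' Shuffles each class with the seed and deals indices round-robin, so
#' per-fold class counts differ by at most one within each class and folds
#' partition the records.
#'
#' @param y Binary label vector.
#' @param k Number of folds (>= 2, at most the minority-class count).
#' @param seed Integer seed.
#' @return Integer fold id (1..k) per record.
#' @export
stratified_kfold <- function(y, k, seed = 1L) {
  if (k < 2) abort("`k` must be at least 2.")
  if (k > min(table(y))) abort("`k` exceeds the minority-class count.")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Balance classes by random oversampling of the minority
#'
#' Duplicates minority-class records uniformly at random with replacement
#' until the class counts are equal. All original records are retained, in
#' their original order, with duplicates appended.
#'
#' @param data Records tibble.
#' @param outcome Outcome column name.
#' @param seed Integer seed.
#' @return Balanced tibble.
#' @export
oversample_minority <- function(data, outcome = "outcome", seed = 1L) {
  tab <- table(data[[outcome]])
  if (length(tab) < 2) abort("both classes must be present.")
  if (tab[1] == tab[2]) return(data)
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(as.integer(tab)))
  set.seed(seed)
  extra <- sample(which(data[[outcome]] == minority), need, replace = TRUE)
  dplyr::bind_rows(data, data[extra, ])
}

#' Remove outlier records via a pluggable detector
#'
#' The detector is any function mapping a numeric feature data frame to a
#' logical flag per record. [detector_none()] flags nothing;
#' [detector_robust_z()] flags records whose mean absolute robust z-score
#' (median/MAD per feature) exceeds a threshold.
#'
#' @param data Records tibble.
#' @param detector Flagging function.
#' @param outcome,id_cols Columns hidden from the detector.
#' @return Tibble without flagged records; attribute `outliers` holds the
#'   flagged row indices.
#' @export
remove_outliers <- function(data, detector = detector_robust_z(),
                            outcome = "outcome",
                            id_cols = c("couple_id", "cycle")) {
  feats <- setdiff(names(data), c(outcome, id_cols))
  flags <- detector(data[feats])
  if (!is.logical(flags) || length(flags) != nrow(data))
    abort("the detector must return one logical flag per record.")
  if (all(flags)) abort("the detector flagged every record.")
  out <- data[!flags, ]
  attr(out, "outliers") <- which(flags)
  out
}

#' @rdname remove_outliers
#' @export
detector_none <- function() function(df) rep(FALSE, nrow(df))

#' @rdname remove_outliers
#' @param threshold Mean absolute robust z-score above which a record is
#'   flagged.
#' @export
detector_robust_z <- function(threshold = 6) {
  function(df) {
    z <- vapply(df, function(x) {
      x <- as.numeric(x)
      s <- mad(x)
      if (s == 0) s <- sd(x)
      if (is.na(s) || s == 0) return(rep(0, length(x)))
      abs(x - median(x)) / s
    }, numeric(nrow(df)))
    if (is.null(dim(z))) z <- matrix(z, nrow = 1)
    rowMeans(z) > threshold
  }
}

#' Fit the full preprocessing pipeline
#'
#' Chains the missing-rate drop, mean/mode imputation, dummy coding, min-max
#' scaling and the correlation filter, remembering every fitted statistic so
#' the identical transformation applies to held-out data via [predict()].
#'
#' @param data Training records tibble.
#' @param outcome Outcome column name.
#' @param missing_threshold Missing-fraction drop threshold.
#' @param low_out,high_in Correlation-filter thresholds.
#' @param id_cols Identifier columns carried through untouched.
#' @return An object of class `psn_preprocess`; `predict(fit, newdata)`
#'   applies the fitted chain, and `fit$data` is the transformed training
#'   table (numeric, complete, in [0, 1]).
#' @export
fit_preprocess <- function(data, outcome = "outcome",
                           missing_threshold = 0.2,
                           low_out = 0.01, high_in = 0.95,
                           id_cols = c("couple_id", "cycle")) {
  step1 <- drop_high_missing(data, outcome, missing_threshold, id_cols)
  step2 <- impute_missing(step1)
  step3 <- dummy_encode(step2, outcome, id_cols)
  step4 <- minmax_normalize(step3, outcome, id_cols)
  step5 <- filter_irrelevant(step4, outcome, low_out, high_in, id_cols)
  fit <- structure(
    list(outcome = outcome, id_cols = id_cols,
         missing_threshold = missing_threshold,
         dropped_features = attr(step1, "report")$dropped_features_missing,
         impute_stats = attr(step2, "params"),
         encoding_map = attr(step3, "map"),
         scaling_params = attr(step4, "params"),
         keep = attr(step5, "keep"),
         report = list(
           dropped_features_missing = attr(step1, "report")$dropped_features_missing,
           dropped_records_missing = attr(step1, "report")$dropped_records_missing,
           dropped_features_correlation = attr(step5, "report")$dropped_features_correlation,
           encoding_map = attr(step3, "map"),
           scaling_params = attr(step4, "params")),
         data = step5),
    class = "psn_preprocess")
  fit
}

#' @rdname fit_preprocess
#' @param object Fitted `psn_preprocess`.
#' @param newdata Records tibble to transform with the fitted statistics.
#' @param ... Unused.
#' @export
predict.psn_preprocess <- function(object, newdata, ...) {
  drop_f <- object$report$dropped_features_missing$feature
  newdata <- newdata[setdiff(names(newdata), drop_f)]
  x <- impute_missing(newdata, stats = object$impute_stats)
  x <- dummy_encode(x, object$outcome, object$id_cols,
                    map = object$encoding_map)
  x <- minmax_normalize(x, object$outcome, object$id_cols,
                        params = object$scaling_params)
  filter_irrelevant(x, object$outcome, id_cols = object$id_cols,
                    keep = object$keep)
}

#' @export
print.psn_preprocess <- function(x, ...) {
  cat("Fitted preprocessing pipeline\n",
      "  features retained: ", length(x$keep), "\n",
      "  features dropped (missingness): ",
      nrow(x$report$dropped_features_missing), "\n",
      "  features dropped (correlation): ",
      nrow(x$report$dropped_features_correlation %||% tibble()), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a preprocessing report to JSON
#' @param fit Fitted `psn_preprocess`.
#' @param path Output path.
#' @export
write_preprocess_report <- function(fit, path) {
  jsonlite::write_json(
    list(dropped_features_missing = fit$report$dropped_features_missing,
         dropped_records_missing = fit$report$dropped_records_missing,
         dropped_features_correlation = fit$report$dropped_features_correlation,
         retained = fit$keep),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
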