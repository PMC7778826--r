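#' Configuration for a synthetic clinical cohort
#'
#' Describes a cohort of couples undergoing repeated treatment cycles, with a
#' mixed-type feature block and a binary per-cycle outcome. The defaults
#' emulate a registry of intrauterine-insemination (IUI) cycles: 86 numeric,
#' 152 binary, 51 nominal and 7 binominal (two-level nominal) features, a
#' marginal positive rate of about 14.4%, and couples contributing one to
#' seven cycles with roughly 72% / 22% / 5% / <1% of couples at 1 / 2 / 3 / >3
#' cycles.
#'
#' The outcome is drawn from a logistic model
#' \eqn{logit(p) = b_0 + \sum_j \beta_j x_j + u_c} over the informative
#' features, where \eqn{u_c} is a couple-level Gaussian random intercept
#' (variance `couple_var`) shared by all cycles of one couple, and the
#' intercept \eqn{b_0} is calibrated numerically so that the marginal positive
#' rate matches `base_rate`.
#'
#' @param n_couples Number of couples.
#' @param cycle_distribution Probability vector over 1..7 cycles per couple;
#'   must sum to 1.
#' @param n_numeric,n_binary,n_nominal,n_binominal Feature counts by type.
#' @param nominal_levels Number of levels per nominal feature (>= 3).
#' @param informative Named numeric vector of log-odds effects; names must be
#'   feature column names (numeric `num_*` or binary `bin_*` features).
#' @param base_rate Target marginal positive probability, in (0, 1).
#' @param missing_rates Named per-feature missing probabilities in [0, 1),
#'   used by [inject_missingness()].
#' @param binary_prob Success probability of the binary features (scalar or
#'   one per feature).
#' @param couple_var Variance of the couple-level random intercept.
#' @param seed Integer seed; identical configs and seeds reproduce identical
#'   cohorts.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_couples = 50, n_numeric = 3, n_binary = 2,
#'                      n_nominal = 1, n_binominal = 0,
#'                      informative = c(num_1 = 1.5), seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_couples = 1000,
                          cycle_distribution = c(0.72, 0.22, 0.05, 0.004,
                                                 0.003, 0.002, 0.001),
                          n_numeric = 86, n_binary = 152,
                          n_nominal = 51, n_binominal = 7,
                          nominal_levels = 4,
                          informative = numeric(0),
                          base_rate = 0.144,
                          missing_rates = numeric(0),
                          binary_prob = 0.5,
                          couple_var = 0.1,
                          seed = 1L) {
  if (n_couples < 1) abort("`n_couples` must be at least 1.")
  if (abs(sum(cycle_distribution) - 1) > 1e-12)
    abort("`cycle_distribution` must sum to 1.")
  if (any(cycle_distribution < 0)) abort("cycle probabilities must be >= 0.")
  counts <- c(n_numeric, n_binary, n_nominal, n_binominal)
  if (any(counts < 0)) abort("feature counts must be non-negative.")
  if (sum(counts) == 0) abort("at least one feature is required.")
  if (base_rate <= 0 || base_rate >= 1)
    abort("`base_rate` must lie strictly inside (0, 1).")
  if (n_nominal > 0 && nominal_levels < 3)
    abort("`nominal_levels` must be >= 3.")
  if (length(missing_rates) && any(missing_rates >= 1 | missing_rates < 0))
    abort("missing rates must lie in [0, 1).")
  structure(
    list(n_couples = as.integer(n_couples),
         cycle_distribution = cycle_distribution,
         n_numeric = as.integer(n_numeric), n_binary = as.integer(n_binary),
         n_nominal = as.integer(n_nominal),
         n_binominal = as.integer(n_binominal),
         nominal_levels = as.integer(nominal_levels),
         informative = informative, base_rate = base_rate,
         missing_rates = missing_rates, binary_prob = binary_prob,
         couple_var = couple_var, seed = as.integer(seed)),
    class = "cohort_config")
}

feature_names_for <- function(config) {
  c(if (config$n_numeric) paste0("num_", seq_len(config$n_numeric)),
    if (config$n_binary) paste0("bin_", seq_len(config$n_binary)),
    if (config$n_nominal) paste0("nom_", seq_len(config$n_nominal)),
    if (config$n_binominal) paste0("bnom_", seq_len(config$n_binominal)))
}

#' Generate a synthetic cohort
#'
#' Draws one record per treatment cycle. Numeric features are standard
#' normal; binary features are Bernoulli; nominal features are uniform
#' categorical draws with levels `L1..Lk`; binominal features are two-level
#' nominal draws (levels `L1`, `L2`), kept distinct from the binary block so
#' a type census of the generated table reproduces the configured counts.
#' The outcome column `outcome` is 0/1.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `couple_id`, `cycle`, the features, and
#'   `outcome`, carrying attributes `types` (named feature-type vector) and
#'   `truth` (informative set, effects, calibrated intercept, couple
#'   intercepts).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_cycles_per <- sample(seq_along(config$cycle_distribution),
                         config$n_couples, replace = TRUE,
                         prob = config$cycle_distribution)
  couple_id <- rep(seq_len(config$n_couples), n_cycles_per)
  cycle <- unlist(lapply(n_cycles_per, seq_len), use.names = FALSE)
  n <- length(couple_id)
  if (n == 0) abort("zero records requested.")

  cols <- list()
  types <- character(0)
  for (j in seq_len(config$n_numeric)) {
    cols[[paste0("num_", j)]] <- rnorm(n)
    types[paste0("num_", j)] <- "numeric"
  }
  bp <- rep(config$binary_prob, length.out = max(config$n_binary, 1))
  for (j in seq_len(config$n_binary)) {
    cols[[paste0("bin_", j)]] <- rbinom(n, 1, bp[j])
    types[paste0("bin_", j)] <- "binary"
  }
  for (j in seq_len(config$n_nominal)) {
    cols[[paste0("nom_", j)]] <-
      sample(paste0("L", seq_len(config$nominal_levels)), n, replace = TRUE)
    types[paste0("nom_", j)] <- "nominal"
  }
  for (j in seq_len(config$n_binominal)) {
    cols[[paste0("bnom_", j)]] <- sample(c("L1", "L2"), n, replace = TRUE)
    types[paste0("bnom_", j)] <- "binominal"
  }
  data <- as_tibble(cols)

  eff <- config$informative
  if (length(eff)) {
    missing_cols <- setdiff(names(eff), names(data))
    if (length(missing_cols))
      abort(paste0("informative features not in table: ",
                   paste(missing_cols, collapse = ", ")))
    bad <- names(eff)[!types[names(eff)] %in% c("numeric", "binary")]
    if (length(bad))
      abort("informative effects are supported on numeric and binary features only.")
  }
  u <- rnorm(config$n_couples, 0, sqrt(config$couple_var))
  eta <- u[couple_id]
  for (nm in names(eff)) eta <- eta + eff[[nm]] * data[[nm]]

  # calibrate the intercept against the realised linear predictor
  f <- function(b0) mean(plogis(b0 + eta)) - config$base_rate
  intercept <- uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
  outcome <- rbinom(n, 1, plogis(intercept + eta))

  out <- dplyr::bind_cols(tibble(couple_id = couple_id, cycle = cycle),
                          data, tibble(outcome = outcome))
  attr(out, "types") <- types
  attr(out, "truth") <- list(informative = names(eff), effects = eff,
                             intercept = intercept, couple_var = config$couple_var)
  out
}

#' Feature types of a generated cohort
#' @param data A cohort tibble from [generate_cohort()].
#' @return Named character vector mapping feature name to
#'   numeric/binary/nominal/binominal.
#' @export
feature_types <- function(data) attr(data, "types")

#' Ground truth of a generated cohort
#' @param data A cohort tibble from [generate_cohort()].
#' @return List with the informative feature set, effects, calibrated
#'   intercept and couple-intercept variance.
#' @export
cohort_truth <- function(data) attr(data, "truth")

#' Mask feature values completely at random
#'
#' Sets each value of each named feature to `NA` independently with the given
#' probability. The outcome column is never maskable.
#'
#' @param data A records tibble.
#' @param rates Named numeric vector of per-feature missing probabilities in
#'   [0, 1). Unnamed scalar applies to every feature column except `outcome`,
#'   `couple_id` and `cycle`.
#' @param outcome Name of the outcome column.
#' @param seed Integer seed.
#' @return The tibble with `NA`s injected; attribute `missing_mask` holds the
#'   logical mask (same shape as the masked columns).
#' @export
inject_missingness <- function(data, rates, outcome = "outcome", seed = 1L) {
  if (is.null(names(rates)) && length(rates) == 1) {
    feats <- setdiff(names(data), c(outcome, "couple_id", "cycle"))
    rates <- setNames(rep(rates, length(feats)), feats)
  }
  if (any(rates >= 1 | rates < 0)) abort("missing rates must lie in [0, 1).")
  if (outcome %in% names(rates))
    abort("the outcome column cannot be masked.")
  unknown <- setdiff(names(rates), names(data))
  if (length(unknown))
    abort(paste0("unknown feature(s): ", paste(unknown, collapse = ", ")))
  set.seed(seed)
  mask <- matrix(FALSE, nrow(data), length(rates),
                 dimnames = list(NULL, names(rates)))
  for (nm in names(rates)) {
    mask[, nm] <- runif(nrow(data)) < rates[[nm]]
    data[[nm]][mask[, nm]] <- NA
  }
  attr(data, "missing_mask") <- mask
  data
}

#' Write a cohort to CSV / its ground truth to JSON
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @param missing_token Text written for `NA` cells (default: empty field).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path, missing_token = "") {
  readr::write_csv(data, path, na = missing_token)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param truth Ground-truth list from [cohort_truth()].
#' @export
write_truth_json <- function(truth, path) {
  if (!is.null(truth$effects)) truth$effects <- as.list(truth$effects)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
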