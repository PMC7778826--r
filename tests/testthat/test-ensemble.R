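test_that("the Q statistic matches its correctness-table definition", {
  truth <- rep(1, 10)
  a <- rep(1, 10); b <- rep(1, 10)
  expect_equal(q_statistic(a, b, truth), 1)  # identical patterns

  # N11=5, N00=3, N01=1, N10=1 -> (15-1)/(15+1) = 0.875
  truth <- rep(1, 10)
  a <- c(rep(1, 5), rep(0, 3), 0, 1)
  b <- c(rep(1, 5), rep(0, 3), 1, 0)
  expect_equal(q_statistic(a, b, truth), 0.875)

  # N11=N00=N01=N10=2 -> 0
  truth <- rep(1, 8)
  a <- c(1, 1, 0, 0, 0, 0, 1, 1)
  b <- c(1, 1, 0, 0, 1, 1, 0, 0)
  expect_equal(q_statistic(a, b, truth), 0)

  # zero denominator, different patterns -> 0
  expect_equal(q_statistic(c(1, 1), c(1, 0), c(1, 1)), 0)
  expect_error(q_statistic(1, c(1, 0), c(1, 0)), "equal length")
})

stub <- function(scores, id) {
  l <- custom_learner(fit = function(x, y) scores,
                      score = function(state, x) state, id = id)
  learner_fit(l, data.frame(x = seq_along(scores)),
              rep(c(0, 1), length.out = length(scores)))
}

test_that("greedy accuracy-diversity selection matches a hand walk", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- data.frame(x = 1:8)
  # A: acc 1.0; B: identical to A; C: acc 0.75, diverse from A
  a <- stub(c(1, 1, 1, 1, 0, 0, 0, 0), "A")
  b <- stub(c(1, 1, 1, 1, 0, 0, 0, 0), "B")
  c_ <- stub(c(1, 1, 1, 0, 0, 0, 0, 1), "C")
  sel <- select_learners(list(a, b, c_), x, y, q_max = 0.9)
  ids <- vapply(sel, `[[`, "", "id")
  # hand walk: A admitted (best); B rejected (|Q| with A = 1); C admitted
  expect_equal(ids, c("A", "C"))
  expect_equal(attr(sel, "accuracy"), c(1, 0.75))

  # identical twins -> exactly one admitted
  sel2 <- select_learners(list(a, b), x, y)
  expect_equal(length(sel2), 1)

  # q_max = 1 admits everyone in accuracy order
  sel3 <- select_learners(list(c_, a, b), x, y, q_max = 1)
  expect_equal(vapply(sel3, `[[`, "", "id"), c("A", "B", "C"))
  expect_error(select_learners(list(), x, y), "empty")
})

test_that("grid search is exhaustive with first-in-grid tie-breaking", {
  set.seed(10)
  n <- 120
  x <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  y <- as.integer(x$f1 + 0.5 * x$f2 + rnorm(n, 0, 0.4) > 0)
  xv <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  yv <- as.integer(xv$f1 + 0.5 * xv$f2 > 0)
  grid <- list(list(maxdepth = 1), list(maxdepth = 2),
               list(maxdepth = 4), list(maxdepth = 8))
  got <- tune_hyperparameters("tree", grid, x, y, xv, yv, seed = 3)
  # independent exhaustive evaluation of each cell
  accs <- vapply(grid, function(p) {
    fit <- learner_fit(base_learner("tree", p), x, y, seed = 3)
    mean(learner_predict(fit, xv) == yv)
  }, numeric(1))
  expect_equal(got$results$accuracy, accs)
  expect_equal(got$params, grid[[which.max(accs)]])
  expect_equal(got$accuracy, max(accs))

  single <- tune_hyperparameters("tree", list(list(maxdepth = 3)),
                                 x, y, xv, yv)
  expect_equal(single$params, list(maxdepth = 3))
  expect_error(tune_hyperparameters("tree", list(), x, y, xv, yv), "empty")
})

test_that("weighted voting aggregates and thresholds as specified", {
  expect_equal(weighted_vote(c(1, 1, 1), c(0.2, 0.5, 0.9)),
               list(label = 1L, score = 1))
  v <- weighted_vote(c(0, 1), c(0.9, 0.3))
  expect_equal(v$score, 0.25)
  expect_equal(v$label, 0L)
  # equal weights reduce to the plain mean; exact 0.5 is positive
  expect_equal(weighted_vote(c(0.2, 0.8), c(1, 1))$score, 0.5)
  expect_equal(weighted_vote(c(0.2, 0.8), c(1, 1))$label, 1L)
  expect_error(weighted_vote(c(1, 0), c(0, 0)), "positive")
  expect_error(weighted_vote(1, c(1, 1)), "equal length")
})

test_that("majority-vote error matches the exhaustive binomial sum", {
  expect_equal(majority_vote_error(1, 0.3), 0.3)
  expect_equal(majority_vote_error(25, 0.5), 0.5)
  # independent summation with choose()
  brute <- sum(vapply(13:25, function(i)
    choose(25, i) * 0.35^i * 0.65^(25 - i), numeric(1)))
  expect_equal(majority_vote_error(25, 0.35), brute, tolerance = 1e-12)
  expect_error(majority_vote_error(4, 0.3), "odd")
  expect_error(majority_vote_error(3, 1.2), "\\[0, 1\\]")
})

test_that("majority-vote error is monotone in committee size and error", {
  ms <- c(1, 3, 5, 9, 15, 25)
  vals <- vapply(ms, majority_vote_error, numeric(1), eps = 0.3)
  expect_true(all(diff(vals) < 0))
  eps_grid <- seq(0.05, 0.45, by = 0.05)
  vals2 <- vapply(eps_grid, function(e) majority_vote_error(9, e),
                  numeric(1))
  expect_true(all(diff(vals2) > 0))
})

test_that("the two-layer error bound obeys the stacking ordering", {
  b <- stacked_error_bound(25, 0.35, 5)
  expect_lt(b$eps_L2, b$eps_L1)
  expect_lt(b$eps_L1, b$eps)
  expect_equal(b$eps_L2, b$bound)          # eps_b2 = eps_L1 attains it
  expect_equal(stacked_error_bound(25, 0.35, 5, eps_b2 = 0)$eps_L2, 0)
  expect_warning(stacked_error_bound(9, 0.2, 3, eps_b2 = 0.4), "premise")
})

test_that("the stacked ensemble nails a linearly separable fixture", {
  set.seed(11)
  n <- 160
  x <- data.frame(f1 = c(rnorm(n / 2, -4), rnorm(n / 2, 4)),
                  f2 = rnorm(n))
  y <- rep(c(0L, 1L), each = n / 2)
  m <- fit_stacked(x, y, families = c("logistic", "tree"), seed = 2)
  expect_equal(mean(predict(m, x) == y), 1.0)
  expect_equal(length(m$vote_weights), length(m$layer2))
  expect_true(all(m$vote_weights >= 0 & m$vote_weights <= 1))
})

test_that("meta-features are one column per admitted layer-1 learner", {
  set.seed(12)
  x <- data.frame(f1 = rnorm(120), f2 = rnorm(120))
  y <- as.integer(x$f1 > 0)
  m <- fit_stacked(x, y, families = c("logistic", "tree", "gbt"), seed = 5)
  meta <- psnstack:::stacked_meta(m, x)
  expect_equal(ncol(meta), length(m$layer1))
  expect_true(all(as.matrix(meta) >= 0 & as.matrix(meta) <= 1))
})

test_that("fitting is deterministic and prediction is row-equivariant", {
  set.seed(13)
  x <- data.frame(f1 = rnorm(150), f2 = rnorm(150))
  y <- as.integer(x$f1 + x$f2 + rnorm(150, 0, 0.5) > 0)
  m1 <- fit_stacked(x, y, families = c("logistic", "random_forest", "gbt"),
                    seed = 7)
  m2 <- fit_stacked(x, y, families = c("logistic", "random_forest", "gbt"),
                    seed = 7)
  expect_equal(predict_score(m1, x), predict_score(m2, x), tolerance = 1e-12)
  perm <- sample(nrow(x))
  expect_equal(predict_score(m1, x[perm, ]), predict_score(m1, x)[perm],
               tolerance = 1e-12)
  expect_equal(predict(m1, x), as.integer(predict_score(m1, x) >= 0.5))
  expect_error(predict_score(m1, x["f1"]), "feature columns")
})

test_that("a frozen tiny model reproduces a manual forward pass", {
  # layer 1: two fixed scorers; layer 2: one scorer averaging its inputs;
  # weights 0.8 -> aggregate = mean of layer-1 scores
  l1a <- custom_learner(function(x, y) list(),
                        function(state, x) x[[1]] * 0 + 0.9, id = "c1")
  l1b <- custom_learner(function(x, y) list(),
                        function(state, x) x[[1]] * 0 + 0.1, id = "c2")
  l2 <- custom_learner(function(x, y) list(),
                       function(state, x) rowMeans(as.matrix(x)), id = "m")
  dummy <- data.frame(f = c(1, 2, 3))
  fit1 <- list(learner_fit(l1a, dummy, c(0, 1, 0)),
               learner_fit(l1b, dummy, c(0, 1, 0)))
  fit2 <- list(learner_fit(l2, data.frame(meta_1 = 1, meta_2 = 0), c(1)))
  model <- structure(list(layer1 = fit1, layer2 = fit2,
                          vote_weights = 0.8, meta = "score",
                          feature_names = "f"),
                     class = "stacked_model")
  # hand walk: layer-1 scores (0.9, 0.1) -> layer-2 mean 0.5 -> weight sum
  # cancels -> aggregate 0.5 -> positive label
  expect_equal(predict_score(model, dummy), rep(0.5, 3))
  expect_equal(predict(model, dummy), rep(1L, 3))
})

test_that("stacking never falls below layer-1 majority voting by much", {
  coh <- make_xor_cohort(n = 600, seed = 21)
  m <- fit_stacked(coh[c("x1", "x2")], coh$outcome,
                   families = c("logistic", "tree", "gbt"), seed = 3)
  # reconstruct the validation split the model used
  set.seed(m$seed)
  y <- coh$outcome
  val_idx <- unlist(lapply(unique(y), function(cls) {
    idx <- which(y == cls)
    sample(idx, round(0.2 * length(idx)))
  }))
  xv <- coh[val_idx, c("x1", "x2")]; yv <- y[val_idx]
  votes <- vapply(m$layer1, learner_predict, numeric(nrow(xv)), x = xv)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(xv))
  mv <- as.integer(rowMeans(votes) >= 0.5)
  acc_mv <- mean(mv == yv)
  acc_stacked <- mean(predict(m, xv) == yv)
  expect_gte(acc_stacked, acc_mv - 0.05)
})

test_that("tidy and glance expose the selection bookkeeping", {
  set.seed(14)
  x <- data.frame(f1 = rnorm(100), f2 = rnorm(100))
  y <- as.integer(x$f1 > 0)
  m <- fit_stacked(x, y, families = c("logistic", "tree"), seed = 4)
  td <- tidy(m)
  expect_true(all(c("layer", "id", "accuracy", "admitted") %in% names(td)))
  expect_setequal(unique(td$layer), c(1L, 2L))
  g <- glance(m)
  expect_equal(g$n_layer1, length(m$layer1))
  expect_equal(g$validation_fraction, 0.2)
})
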