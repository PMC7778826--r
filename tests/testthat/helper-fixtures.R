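# Shared fixtures, built in code at test time.

# The frozen six-node network triple exercising every Table-of-features
# branch: a triangle positive-class network, a path negative-class network,
# and a bridged combined network.
fixture_triple <- function(swap = FALSE) {
  cn1 <- make_network(
    c("q", "p1", "p2", "n1", "n2", "n3"),
    tibble::tibble(
      from = c("q", "q", "p1", "q", "n1", "n2", "p2"),
      to = c("p1", "p2", "p2", "n1", "n2", "n3", "n1"),
      weight = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 0.9)))
  cn2 <- make_network(
    c("q", "p1", "p2"),
    tibble::tibble(from = c("q", "q", "p1"), to = c("p1", "p2", "p2"),
                   weight = c(0.2, 0.3, 0.4)))
  cn3 <- make_network(
    c("q", "n1", "n2", "n3"),
    tibble::tibble(from = c("q", "n1", "n2"), to = c("n1", "n2", "n3"),
                   weight = c(0.5, 0.6, 0.8)))
  if (swap) make_triple(cn1, cn3, cn2) else make_triple(cn1, cn2, cn3)
}

# the 17 values of the fixture, frozen from exhaustive-enumeration oracles
# (eigenvector entries from dense eigendecomposition: CN1 0.52997260,
# CN2 = 1/sqrt(3), CN3 end-of-path = 1/sqrt(2 + 2*phi^2))
fixture_expected <- c(
  F1 = 1 / 3, F2 = 0, F3 = 48 / 7, F4 = 0.3879488023, F5 = 0, F6 = 1.5,
  F7 = 0.4, F8 = 1, F9 = 2, F10 = 7, F11 = 1.5530687876, F12 = 0,
  F13 = 0.5, F14 = 2 / 7, F15 = 0.3819660113, F16 = 0, F17 = 1)

# XOR-like two-feature cohort: nonlinear class structure no single linear
# learner can separate
make_xor_cohort <- function(n = 2000, seed = 1, noise = 0.02) {
  set.seed(seed)
  x1 <- stats::runif(n); x2 <- stats::runif(n)
  y <- as.integer(xor(x1 > 0.5, x2 > 0.5))
  flip <- stats::runif(n) < noise
  y[flip] <- 1L - y[flip]
  tibble::tibble(x1 = x1, x2 = x2, outcome = y)
}

# small geometric cohort: positives on a ring, negatives in the centre --
# class structure visible to similarity networks but not to a linear model
make_ring_cohort <- function(n = 200, seed = 1) {
  set.seed(seed)
  n_pos <- n %/% 2
  theta <- stats::runif(n_pos, 0, 2 * pi)
  r <- stats::rnorm(n_pos, 1, 0.08)
  pos <- tibble::tibble(x1 = r * cos(theta), x2 = r * sin(theta),
                        outcome = 1L)
  neg <- tibble::tibble(x1 = stats::rnorm(n - n_pos, 0, 0.25),
                        x2 = stats::rnorm(n - n_pos, 0, 0.25), outcome = 0L)
  d <- dplyr::bind_rows(pos, neg)
  d[sample(nrow(d)), ]
}

# cohort with planted informative numeric features among noise
make_planted_cohort <- function(n_couples = 250, n_noise = 25,
                                n_signal = 5, effect = 2, seed = 1) {
  eff <- stats::setNames(rep(effect, n_signal) * c(1, -1, 1, -1, 1)[
    seq_len(n_signal)], paste0("num_", seq_len(n_signal)))
  cfg <- psnstack::cohort_config(
    n_couples = n_couples, n_numeric = n_signal + n_noise, n_binary = 0,
    n_nominal = 0, n_binominal = 0, informative = eff, base_rate = 0.4,
    couple_var = 0, seed = seed)
  psnstack::generate_cohort(cfg)
}

drop_ids <- function(data) {
  data[setdiff(names(data), c("couple_id", "cycle"))]
}

features_of <- function(data, outcome = "outcome") {
  data[setdiff(names(data), c("couple_id", "cycle", outcome))]
}
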