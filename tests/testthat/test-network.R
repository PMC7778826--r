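test_that("pairwise distance is Euclidean, symmetric and guarded", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(1:4, 1:4), 0)
  set.seed(1)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  expect_error(pairwise_distance(1:3, 1:4), "dimensions")
})

test_that("network construction follows the threshold and weight rules", {
  # three records on a line at 0, 1, 3: mean distance (1+3+2)/3 = 2,
  # tau = 0.7 * 2 = 1.4 -> single edge r1-r2, weight 1/3
  x <- matrix(c(0, 1, 3), ncol = 1)
  net <- build_network(x, tau_factor = 0.7)
  expect_equal(net$tau, 1.4)
  e <- network_edges(net)
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$from, e$to), c("r1", "r2"))
  expect_equal(e$weight, 1 / 3)

  full <- build_network(x, tau_factor = 10)
  expect_equal(unname(network_size(full)["edges"]), 3)
  empty <- build_network(x, tau_factor = 1e-9)
  expect_equal(unname(network_size(empty)["edges"]), 0)
  expect_error(build_network(matrix(1, 3, 2)), "degenerate")
})

test_that("duplicate records keep a zero-weight edge", {
  x <- matrix(c(0, 0, 5), ncol = 1)
  net <- build_network(x, tau_factor = 0.5)  # tau = 0.5 * 10/3 ~ 1.67
  e <- network_edges(net)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 0)
  m <- node_metrics(net)   # zero weights route through the exact fallback
  expect_true(all(is.finite(m$betweenness)))
  expect_equal(m$min_shortest_path[m$node == "r1"], 0)
})

test_that("the network triple obeys the node-set and leakage conventions", {
  set.seed(3)
  train <- tibble::tibble(f1 = rnorm(10), f2 = rnorm(10),
                          outcome = rep(c(1, 0), c(4, 6)))
  tr <- build_triple(train, query = tibble::tibble(f1 = 0, f2 = 0))
  expect_equal(unname(network_size(tr$cn1)["nodes"]), 11)
  expect_equal(unname(network_size(tr$cn2)["nodes"]), 5)
  expect_equal(unname(network_size(tr$cn3)["nodes"]), 7)
  expect_equal(intersect(tr$cn2$nodes, tr$cn3$nodes), "q")
  expect_equal(tr$cn2$tau, tr$cn1$tau)
  expect_equal(tr$cn3$tau, tr$cn1$tau)

  # a positive training record as query loses its labelled copy everywhere
  tr2 <- build_triple(train, query_row = 1)
  expect_equal(unname(network_size(tr2$cn1)["nodes"]), 10)
  expect_equal(unname(network_size(tr2$cn2)["nodes"]), 4)
  expect_equal(unname(network_size(tr2$cn3)["nodes"]), 7)

  no_pos <- dplyr::mutate(train, outcome = 0)
  expect_error(build_triple(no_pos, query = tibble::tibble(f1 = 0, f2 = 0)),
               "both classes")
})

test_that("CN2/CN3 edges between training nodes also exist in CN1", {
  set.seed(9)
  train <- tibble::tibble(f1 = rnorm(30), f2 = rnorm(30),
                          outcome = rbinom(30, 1, 0.4))
  tr <- build_triple(train, query = tibble::tibble(f1 = 0.1, f2 = -0.2))
  e1 <- network_edges(tr$cn1)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  for (net in list(tr$cn2, tr$cn3)) {
    e <- network_edges(net)
    expect_true(all(key(e) %in% key(e1)))  # same tau, subset geometry
  }
})

test_that("textbook node metrics come out exactly", {
  path <- make_network(c("A", "B", "C"),
                       tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                      weight = c(1, 1)))
  m <- node_metrics(path)
  expect_equal(m$degree[m$node == "B"], 2)
  expect_equal(m$closeness[m$node == "B"], 0.5)
  expect_equal(m$min_shortest_path[m$node == "A"], 1)
  expect_equal(m$two_hop[m$node == "A"], 2)
  expect_equal(m$betweenness[m$node == "B"], 1)

  star <- make_network(c("c", "l1", "l2", "l3"),
                       tibble::tibble(from = rep("c", 3),
                                      to = c("l1", "l2", "l3"),
                                      weight = rep(0.5, 3)))
  ms <- node_metrics(star)
  expect_equal(ms$betweenness[ms$node == "c"], 3)
  expect_true(all(ms$betweenness[ms$node != "c"] == 0))
  expect_equal(ms$clustering[ms$node == "c"], 0)

  tri <- make_network(c("a", "b", "c"),
                      tibble::tibble(from = c("a", "a", "b"),
                                     to = c("b", "c", "c"),
                                     weight = c(0.2, 0.4, 0.3)))
  expect_equal(clustering_coefficient(tri, "a"), 1)

  # neighbours {a, b, c} of v with a-b the only neighbour edge -> 1/3
  wedge <- make_network(
    c("v", "a", "b", "c"),
    tibble::tibble(from = c("v", "v", "v", "a"), to = c("a", "b", "c", "b"),
                   weight = rep(1, 4)))
  expect_equal(clustering_coefficient(wedge, "v"), 1 / 3)

  k4 <- make_network(c("a", "b", "c", "d"),
                     tibble::tibble(from = c("a", "a", "a", "b", "b", "c"),
                                    to = c("b", "c", "d", "c", "d", "d"),
                                    weight = rep(1, 6)))
  ev <- node_metrics(k4)$eigenvector
  expect_equal(ev, rep(0.5, 4))  # symmetric, L2-normalised
})

test_that("isolated nodes hit their sentinel values", {
  g <- make_network(c("a", "b", "iso"),
                    tibble::tibble(from = "a", to = "b", weight = 0.4))
  m <- node_metrics(g)
  iso <- m[m$node == "iso", ]
  expect_equal(iso$degree, 0)
  expect_equal(iso$weighted_degree, 0)
  expect_equal(iso$closeness, 0)
  expect_equal(iso$eigenvector, 0)
  expect_equal(iso$betweenness, 0)
  expect_equal(iso$clustering, 0)
  expect_equal(iso$two_hop, 0)
  expect_true(is.infinite(iso$min_shortest_path))
  expect_error(compute_node_metrics(g, "nope"), "not present")
})

test_that("metrics agree with brute-force oracles on assorted small graphs", {
  # focused set here (incl. disconnected and near-complete); the large
  # randomised sweep lives with the acceptance suite
  for (s in 1:40) {
    net <- random_small_network(n = sample(3:7, 1), p = runif(1, 0.2, 0.9),
                                seed = 1000 + s)
    expect_true(isTRUE(compare_with_oracle(net)),
                label = sprintf("graph seed %d metric %s", s,
                                compare_with_oracle(net)))
  }
})

test_that("adding an edge never decreases local connectivity metrics", {
  base_edges <- tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                               weight = c(0.3, 0.6))
  g1 <- make_network(c("a", "b", "c", "d"), base_edges)
  g2 <- make_network(c("a", "b", "c", "d"),
                     dplyr::bind_rows(base_edges,
                                      tibble::tibble(from = "c", to = "d",
                                                     weight = 0.2)))
  m1 <- node_metrics(g1); m2 <- node_metrics(g2)
  for (v in c("c", "d")) {
    expect_gte(m2$degree[m2$node == v], m1$degree[m1$node == v])
    expect_gte(m2$weighted_degree[m2$node == v],
               m1$weighted_degree[m1$node == v])
    expect_gte(m2$two_hop[m2$node == v], m1$two_hop[m1$node == v])
  }
})

test_that("a lower threshold yields a nested, sparser edge set", {
  set.seed(4)
  x <- matrix(rnorm(40), ncol = 2)
  small <- build_network(x, tau_factor = 0.4)
  large <- build_network(x, tau_factor = 0.9)
  key <- function(net) {
    e <- network_edges(net)
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  expect_true(all(key(small) %in% key(large)))
  expect_lt(nrow(network_edges(small)), nrow(network_edges(large)))
})

test_that("community partitioning is a proper partition and splits cliques", {
  set.seed(5)
  x <- matrix(rnorm(200), ncol = 2)
  net <- partition_communities(build_network(x, 0.7), size_limit = 2000)
  expect_equal(unname(unique(net$community)), 1L)
  m_whole <- node_metrics(build_network(x, 0.7))
  expect_equal(node_metrics(net), m_whole)

  # two 6-cliques joined by one bridge, forced past the size limit
  cl <- function(prefix) {
    nodes <- paste0(prefix, 1:6)
    pairs <- t(utils::combn(6, 2))
    tibble::tibble(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                   weight = 0.2)
  }
  edges <- dplyr::bind_rows(cl("a"), cl("b"),
                            tibble::tibble(from = "a1", to = "b1",
                                           weight = 0.9))
  g <- make_network(c(paste0("a", 1:6), paste0("b", 1:6)), edges)
  part <- partition_communities(g, size_limit = 5, seed = 1)
  expect_equal(length(part$community), 12)
  expect_true(all(!is.na(part$community)))
  expect_equal(length(unique(part$community[paste0("a", 1:6)])), 1)
  expect_equal(length(unique(part$community[paste0("b", 1:6)])), 1)
  expect_false(part$community[["a1"]] == part$community[["b1"]])
})

test_that("networks export to GraphML", {
  net <- make_network(c("a", "b"), tibble::tibble(from = "a", to = "b",
                                                  weight = 0.5))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 2)
  expect_equal(igraph::E(back)$weight, 0.5)
})
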