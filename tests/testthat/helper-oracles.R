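# Brute-force graph oracles, independent of the package's metric code:
# shortest paths by exhaustive simple-path enumeration, eigenvector by
# dense eigendecomposition. Only usable on tiny graphs (<= ~8 nodes).

# direct psn_network constructor for hand-built fixtures
make_network <- function(nodes, edges, tau = 1) {
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  } else {
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
  }
  structure(list(graph = g, tau = tau, tau_factor = NA_real_,
                 max_dist = if (nrow(edges)) max(edges$weight, 1) else 1,
                 nodes = nodes, community = NULL),
            class = c("psn_network"))
}

make_triple <- function(cn1, cn2, cn3, query = "q") {
  structure(list(cn1 = cn1, cn2 = cn2, cn3 = cn3, query = query,
                 tau = cn1$tau), class = "psn_triple")
}

# adjacency list of an edge tibble
edge_list_of <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$weight[i]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, w = w))
  }
  adj
}

# all simple paths from a to b; returns list of (path nodes, length)
enumerate_paths <- function(adj, a, b) {
  out <- list()
  recurse <- function(path, len) {
    cur <- path[length(path)]
    if (cur == b) {
      out[[length(out) + 1]] <<- list(path = path, len = len)
      return()
    }
    nb <- adj[[cur]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      nxt <- nb$to[i]
      if (nxt %in% path) next
      recurse(c(path, nxt), len + nb$w[i])
    }
  }
  recurse(a, 0)
  out
}

oracle_shortest <- function(adj, a, b, tol = 1e-9) {
  ps <- enumerate_paths(adj, a, b)
  if (!length(ps)) return(list(dist = Inf, paths = list()))
  lens <- vapply(ps, `[[`, numeric(1), "len")
  d <- min(lens)
  list(dist = d, paths = ps[lens <= d + tol])
}

oracle_metrics <- function(network) {
  nodes <- network$nodes
  edges <- psnstack::network_edges(network)
  if (!"weight" %in% names(edges))   # edgeless graph: no edge attributes
    edges$weight <- numeric(nrow(edges))
  adj <- edge_list_of(nodes, edges)
  n <- length(nodes)
  sp <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(sp) <- 0
  shortest_paths <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    r <- oracle_shortest(adj, nodes[i], nodes[j])
    sp[i, j] <- sp[j, i] <- r$dist
    shortest_paths[[paste(i, j)]] <- r$paths
  }
  deg <- vapply(nodes, function(v)
    sum(edges$from == v | edges$to == v), numeric(1))
  wdeg <- vapply(nodes, function(v)
    sum(edges$weight[edges$from == v | edges$to == v]), numeric(1))
  closeness <- vapply(seq_len(n), function(i) {
    d <- sp[i, -i]; d <- d[is.finite(d)]
    if (!length(d) || sum(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  msp <- vapply(seq_len(n), function(i) {
    d <- sp[i, -i]; d <- d[is.finite(d)]
    if (!length(d)) Inf else min(d)
  }, numeric(1))
  btw <- vapply(nodes, function(v) {
    tot <- 0
    for (key in names(shortest_paths)) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      if (nodes[ij[1]] == v || nodes[ij[2]] == v) next
      paths <- shortest_paths[[key]]
      if (!length(paths)) next
      through <- sum(vapply(paths, function(p) v %in% p$path, logical(1)))
      tot <- tot + through / length(paths)
    }
    tot
  }, numeric(1))
  has_edge <- function(a, b)
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  clust <- vapply(nodes, function(v) {
    nb <- unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
      if (has_edge(nb[i], nb[j])) tri <- tri + 1
    tri / choose(k, 2)
  }, numeric(1))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$from[i], edges$to[i]] <- 1
    A[edges$to[i], edges$from[i]] <- 1
  }
  # per-component L2-normalised principal eigenvector via eigen()
  eig <- numeric(n)
  comp_of <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp_of[i])) next
    cid <- cid + 1
    members <- which(is.finite(sp[i, ]))
    comp_of[members] <- cid
  }
  for (k in unique(comp_of)) {
    members <- which(comp_of == k)
    if (length(members) < 2 || sum(A[members, members]) == 0) next
    ev <- eigen(A[members, members, drop = FALSE], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    eig[members] <- v / sqrt(sum(v^2))
  }
  two_hop <- vapply(seq_len(n), function(i) {
    d1 <- which(A[i, ] > 0)
    d2 <- unique(unlist(lapply(d1, function(j) which(A[j, ] > 0))))
    length(setdiff(union(d1, d2), i))
  }, numeric(1))
  tibble::tibble(node = nodes, degree = unname(deg),
                 weighted_degree = unname(wdeg),
                 closeness = closeness, eigenvector = eig,
                 betweenness = unname(btw), clustering = unname(clust),
                 min_shortest_path = msp, two_hop = two_hop)
}

# random small network with positive distinct-ish weights
random_small_network <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- tibble::tibble(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]],
                          weight = stats::runif(sum(keep), 0.05, 1))
  make_network(nodes, edges)
}

compare_with_oracle <- function(network, tol = 1e-8) {
  got <- psnstack::node_metrics(network)
  want <- oracle_metrics(network)
  cols <- c("degree", "weighted_degree", "closeness", "eigenvector",
            "betweenness", "clustering", "min_shortest_path", "two_hop")
  for (cl in cols) {
    g <- got[[cl]]; w <- want[[cl]]
    both_inf <- is.infinite(g) & is.infinite(w)
    if (!all(both_inf == (is.infinite(g) | is.infinite(w)))) return(cl)
    if (any(abs(g[!both_inf] - w[!both_inf]) > tol)) return(cl)
  }
  TRUE
}
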