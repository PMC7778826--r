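#' Euclidean distance between two records
#'
#' @param a,b Numeric vectors of equal length (feature values only; the
#'   outcome is never part of the geometry).
#' @return Non-negative distance.
#' @export
pairwise_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("records have different dimensions.")
  sqrt(sum((a - b)^2))
}

# Internal constructor from a full symmetric distance matrix.
# tau may be supplied (shared across a network triple) or derived from this
# matrix as tau_factor * mean pairwise distance. Edge rule: distance < tau.
# Edge weight: distance / max pairwise distance over all node pairs, so a
# zero-distance duplicate pair keeps its edge with weight 0.
network_from_dist <- function(D, ids, tau_factor, tau = NULL) {
  n <- nrow(D)
  ut <- upper.tri(D)
  max_d <- max(D[ut])
  if (max_d == 0)
    abort("degenerate geometry: all records are identical.")
  if (is.null(tau)) tau <- tau_factor * mean(D[ut])
  sel <- which(ut & D < tau, arr.ind = TRUE)
  edges <- tibble(from = ids[sel[, 1]], to = ids[sel[, 2]],
                  weight = D[sel] / max_d)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  structure(list(graph = g, tau = tau, tau_factor = tau_factor,
                 max_dist = max_d, nodes = ids, community = NULL),
            class = "psn_network")
}

#' Build a patient-similarity network
#'
#' Nodes are records; an edge joins two records whose Euclidean distance is
#' strictly below the threshold \eqn{\tau = \tau_{factor} \times} mean of all
#' pairwise distances. Edge weights are distances divided by the maximum
#' pairwise distance over all node pairs, hence in [0, 1]; an exact-duplicate
#' pair keeps its edge with weight 0. The graph is undirected with no
#' self-loops.
#'
#' @param records Numeric matrix or data frame of records (rows) by features;
#'   no outcome column.
#' @param tau_factor Positive multiplier of the mean pairwise distance.
#' @param ids Optional node identifiers (default `r1..rn`).
#' @param tau Optional explicit threshold, overriding the derived one (used
#'   to share a threshold across the three networks of a triple).
#' @return An object of class `psn_network`.
#' @export
build_network <- function(records, tau_factor = 0.7, ids = NULL, tau = NULL) {
  m <- as.matrix(records)
  if (nrow(m) < 2) abort("at least two records are required.")
  if (tau_factor <= 0 && is.null(tau)) abort("`tau_factor` must be positive.")
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(m)))
  D <- as.matrix(dist(m))
  network_from_dist(D, ids, tau_factor, tau)
}

#' Number of nodes / edges of a similarity network
#' @param network A `psn_network`.
#' @export
network_size <- function(network) {
  c(nodes = igraph::vcount(network$graph),
    edges = igraph::ecount(network$graph))
}

#' @export
print.psn_network <- function(x, ...) {
  s <- network_size(x)
  cat(sprintf("Patient-similarity network: %d nodes, %d edges, tau = %.4g\n",
              s[1], s[2], x$tau))
  invisible(x)
}

#' Edges of a similarity network as a tibble
#' @param network A `psn_network`.
#' @return Tibble with `from`, `to`, `weight`.
#' @export
network_edges <- function(network) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  as_tibble(e)
}

#' Build the CN1/CN2/CN3 network triple for one query record
#'
#' CN1 spans the query plus all training records, CN2 the query plus the
#' positive-labelled training records, CN3 the query plus the
#' negative-labelled ones. The class label never enters the geometry. When
#' the query is itself a training record (`query_row` given), its labelled
#' copy is removed from all three node sets, so it appears as the unlabelled
#' query node only. The distance threshold \eqn{\tau} is derived from CN1's
#' node set and shared by all three networks; edge weights are normalised by
#' each network's own maximum pairwise distance.
#'
#' @param training Preprocessed training tibble containing `outcome`.
#' @param query One-row tibble / numeric vector of preprocessed feature
#'   values (no outcome), or `NULL` when `query_row` is given.
#' @param outcome Outcome column name in `training`.
#' @param tau_factor Threshold multiplier shared by the three networks.
#' @param query_row Row index of `training` to treat as the query.
#' @param id_cols Identifier columns excluded from the geometry.
#' @return An object of class `psn_triple` with elements `cn1`, `cn2`, `cn3`
#'   and `query` (the query node id, `"q"`).
#' @export
build_triple <- function(training, query = NULL, outcome = "outcome",
                         tau_factor = 0.7, query_row = NULL,
                         id_cols = c("couple_id", "cycle")) {
  feats <- setdiff(names(training), c(outcome, id_cols))
  y <- training[[outcome]]
  if (length(unique(y)) < 2) abort("both classes must be present in training.")
  if (!is.null(query_row)) {
    query <- training[query_row, feats]
    training <- training[-query_row, ]
    y <- y[-query_row]
    if (length(unique(y)) < 2)
      abort("removing the query left a single-class training set.")
  }
  if (is.null(query)) abort("either `query` or `query_row` is required.")
  q <- as.numeric(as.data.frame(query)[1, feats, drop = TRUE])
  X <- as.matrix(training[feats])
  full <- rbind(q, X)
  ids <- c("q", paste0("r", seq_len(nrow(X))))
  D <- as.matrix(dist(full))
  dimnames(D) <- list(ids, ids)
  triple_from_dist(D, y, tau_factor)
}

# Shared-threshold triple construction from the CN1 distance matrix whose
# first row/col is the query.
triple_from_dist <- function(D, y, tau_factor) {
  ids <- rownames(D)
  pos <- c(1L, 1L + which(y == 1))
  neg <- c(1L, 1L + which(y == 0))
  cn1 <- network_from_dist(D, ids, tau_factor)
  cn2 <- network_from_dist(D[pos, pos, drop = FALSE], ids[pos], tau_factor,
                           tau = cn1$tau)
  cn3 <- network_from_dist(D[neg, neg, drop = FALSE], ids[neg], tau_factor,
                           tau = cn1$tau)
  structure(list(cn1 = cn1, cn2 = cn2, cn3 = cn3, query = "q",
                 tau = cn1$tau),
            class = "psn_triple")
}

#' @export
print.psn_triple <- function(x, ...) {
  cat(sprintf(
    "Network triple (tau = %.4g): CN1 %d nodes, CN2 %d, CN3 %d; query '%s'\n",
    x$tau, igraph::vcount(x$cn1$graph), igraph::vcount(x$cn2$graph),
    igraph::vcount(x$cn3$graph), x$query))
  invisible(x)
}

#' Partition a large network into communities
#'
#' When the network exceeds `size_limit` nodes, Louvain modularity
#' optimisation on the unweighted skeleton assigns every node a community,
#' and node metrics are subsequently computed on each node's community
#' induced subgraph (a complexity-control device for very large cohorts).
#' At or below the limit, all nodes share one community and metrics equal
#' whole-network metrics.
#'
#' @param network A `psn_network`.
#' @param size_limit Node count above which partitioning engages.
#' @param seed Integer seed (community detection is seeded, hence
#'   deterministic).
#' @return The network with a `community` assignment (named integer vector).
#' @export
partition_communities <- function(network, size_limit = 2000, seed = 1L) {
  n <- igraph::vcount(network$graph)
  if (n <= size_limit) {
    network$community <- setNames(rep(1L, n), network$nodes)
    return(network)
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(network$graph, weights = NA)
  network$community <- setNames(as.integer(igraph::membership(cl)),
                                network$nodes)
  network
}

# ---- node-level metrics ----------------------------------------------------

# L2-normalised principal eigenvector of the binary adjacency, computed per
# connected component by shifted power iteration (A + I keeps the dominant
# eigenvalue unique on bipartite components). Isolated nodes score 0.
eigenvector_centrality_l2 <- function(g, tol = 1e-10, max_iter = 100000L) {
  n <- igraph::vcount(g)
  res <- numeric(n)
  comp <- igraph::components(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) == 1) next
    Ak <- A[members, members, drop = FALSE]
    if (sum(Ak) == 0) next
    v <- rep(1 / sqrt(length(members)), length(members))
    for (it in seq_len(max_iter)) {
      w <- as.numeric(Ak %*% v) + v      # shift by +I
      w <- w / sqrt(sum(w^2))
      if (max(abs(w - v)) < tol) { v <- w; break }
      v <- w
    }
    res[members] <- abs(v)
  }
  res
}

# Exact weighted betweenness (Brandes) tolerating zero edge weights; used
# when igraph's implementation refuses non-positive weights. O(n^3)-ish, for
# the rare duplicate-record graphs only.
brandes_betweenness <- function(g, tol = 1e-12) {
  n <- igraph::vcount(g)
  bc <- numeric(n)
  if (igraph::ecount(g) == 0) return(bc)
  adj <- lapply(seq_len(n), function(v) {
    es <- igraph::incident(g, v)
    ends <- igraph::ends(g, es, names = FALSE)
    nb <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    cbind(nb, igraph::edge_attr(g, "weight", es))
  })
  for (s in seq_len(n)) {
    dist_s <- rep(Inf, n); dist_s[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    settled <- logical(n)
    order_settled <- integer(0)
    repeat {
      cand <- which(!settled & is.finite(dist_s))
      if (!length(cand)) break
      u <- cand[which.min(dist_s[cand])]
      settled[u] <- TRUE
      order_settled <- c(order_settled, u)
      nb <- adj[[u]]
      if (nrow(nb)) for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; w <- nb[r, 2]
        alt <- dist_s[u] + w
        if (alt < dist_s[v] - tol) {
          dist_s[v] <- alt; sigma[v] <- sigma[u]; preds[[v]] <- u
        } else if (abs(alt - dist_s[v]) <= tol && !settled[v]) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (u in rev(order_settled)) {
      for (p in preds[[u]])
        delta[p] <- delta[p] + sigma[p] / sigma[u] * (1 + delta[u])
      if (u != s) bc[u] <- bc[u] + delta[u]
    }
  }
  bc / 2  # undirected: each pair counted from both endpoints
}

#' Node-level graph statistics for every node of a network
#'
#' Computes, per node: `degree` (edge count), `weighted_degree` (sum of
#' adjacent edge weights), `closeness` (reciprocal of the summed weighted
#' shortest-path lengths to reachable nodes; 0 for an isolated node),
#' `eigenvector` (principal-eigenvector entry of the binary adjacency of the
#' node's component, L2-normalised, power iteration at tolerance 1e-10),
#' `betweenness` (weighted shortest-path pair share), `clustering`
#' (triangles over neighbour pairs; 0 below degree 2), `min_shortest_path`
#' (weighted distance to the nearest other reachable node; `Inf` if
#' isolated), `two_hop` (nodes within unweighted distance 2, excluding
#' self), and each metric's `norm_*` variant divided by its maximum over the
#' network's nodes.
#'
#' Path-based metrics treat the edge weight (a normalised distance) as a
#' length; count-based metrics use the binary adjacency. If the network has
#' been partitioned by [partition_communities()], metrics are computed on
#' each node's community induced subgraph.
#'
#' @param network A `psn_network`.
#' @return Tibble, one row per node.
#' @export
node_metrics <- function(network) {
  g <- network$graph
  comm <- network$community
  if (!is.null(comm) && length(unique(comm)) > 1) {
    parts <- lapply(split(names(comm), comm), function(nodes) {
      sub <- network
      sub$graph <- igraph::induced_subgraph(g, nodes)
      sub$nodes <- nodes
      sub$community <- NULL
      node_metrics(sub)
    })
    out <- dplyr::bind_rows(parts)
    return(out[match(network$nodes, out$node), ])
  }
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  deg <- igraph::degree(g)
  wdeg <- igraph::strength(g, weights = w)
  Dw <- igraph::distances(g, weights = w)
  closeness <- vapply(seq_len(n), function(i) {
    d <- Dw[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    s <- sum(d)
    if (s == 0) 0 else 1 / s  # all-duplicate component: defined as 0
  }, numeric(1))
  msp <- vapply(seq_len(n), function(i) {
    d <- Dw[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) Inf else min(d)
  }, numeric(1))
  eig <- eigenvector_centrality_l2(g)
  btw <- if (igraph::ecount(g) == 0) numeric(n)
         else if (length(w) && min(w) > 0) igraph::betweenness(g, weights = w)
         else brandes_betweenness(g)
  clust <- igraph::transitivity(g, type = "local", isolates = "zero")
  two_hop <- igraph::ego_size(g, order = 2, mindist = 1)
  norm <- function(x) {
    fin <- x[is.finite(x)]
    m <- if (length(fin)) max(fin) else 0
    if (m == 0) ifelse(is.finite(x), 0, x) else x / m
  }
  tibble(node = network$nodes,
         degree = as.numeric(deg), weighted_degree = as.numeric(wdeg),
         closeness = closeness, eigenvector = eig,
         betweenness = as.numeric(btw), clustering = as.numeric(clust),
         min_shortest_path = msp, two_hop = as.numeric(two_hop),
         norm_degree = norm(as.numeric(deg)),
         norm_weighted_degree = norm(as.numeric(wdeg)),
         norm_closeness = norm(closeness), norm_eigenvector = norm(eig),
         norm_betweenness = norm(as.numeric(btw)),
         norm_clustering = norm(as.numeric(clust)),
         norm_two_hop = norm(as.numeric(two_hop)))
}

#' @rdname node_metrics
#' @param node Node identifier.
#' @return For `compute_node_metrics`, the single matching row.
#' @export
compute_node_metrics <- function(network, node) {
  if (!node %in% network$nodes) abort(sprintf("node '%s' not present.", node))
  m <- node_metrics(network)
  m[m$node == node, ]
}

#' Betweenness centrality of one node
#'
#' Sum over unordered node pairs of the fraction of weighted shortest paths
#' between the pair that pass through the node; unreachable pairs contribute
#' zero.
#'
#' @param network A `psn_network`.
#' @param node Node identifier.
#' @return Non-negative value.
#' @export
betweenness_centrality <- function(network, node) {
  compute_node_metrics(network, node)$betweenness
}

#' Local clustering coefficient of one node
#'
#' Triangles containing the node divided by the number of pairs of its
#' neighbours; 0 by convention below degree 2.
#'
#' @inheritParams betweenness_centrality
#' @return Value in [0, 1].
#' @export
clustering_coefficient <- function(network, node) {
  compute_node_metrics(network, node)$clustering
}

#' Export a network to GraphML
#'
#' Node ids, edge weights and (if assigned) community ids are written, for
#' inspection in external graph tools.
#'
#' @param network A `psn_network`.
#' @param path Output file path.
#' @export
write_network_graphml <- function(network, path) {
  g <- network$graph
  if (!is.null(network$community))
    igraph::V(g)$community <- as.integer(network$community[network$nodes])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
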