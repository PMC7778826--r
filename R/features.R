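#' Capped safe division
#'
#' Division with fixed conventions at a zero denominator: `0/0` is 0, a
#' non-zero numerator over 0 returns `cap` with the numerator's sign, and
#' any finite quotient is clamped to `[-cap, cap]`.
#'
#' @param num,den Numerator and denominator.
#' @param cap Positive magnitude bound (default 10).
#' @return A finite value in `[-cap, cap]`.
#' @export
safe_ratio <- function(num, den, cap = 10) {
  if (cap <= 0) abort("`cap` must be positive.")
  if (den == 0) {
    if (num == 0) return(0)
    return(cap * sign(num))
  }
  r <- num / den
  sign(r) * min(abs(r), cap)
}

# ratio of possibly-infinite minimum shortest-path lengths (F7):
# Inf/Inf -> 1, finite/Inf -> 0, Inf/finite -> cap, else safe_ratio
msp_ratio <- function(num, den, cap = 10) {
  if (is.infinite(num) && is.infinite(den)) return(1)
  if (is.infinite(den)) return(0)
  if (is.infinite(num)) return(cap)
  safe_ratio(num, den, cap)
}

#' Engineer the 17 centrality-contrast features from a network triple
#'
#' For the query node, contrasts its graph statistics between the
#' positive-class network (CN2) and the negative-class network (CN3):
#'
#' * F1-F6: (metric in CN2 - metric in CN3) / metric in CN1, for degree,
#'   weighted degree, closeness, eigenvector centrality, betweenness and
#'   clustering coefficient;
#' * F7: ratio of the minimum weighted shortest-path length in CN2 to that
#'   in CN3 (distance to the nearest node in each class network);
#' * F8: ratio of two-hop neighbour counts CN2 / CN3;
#' * F9-F12: plain CN2 / CN3 ratios of degree, closeness, eigenvector and
#'   betweenness;
#' * F13-F17: (normalised metric in CN2 - normalised metric in CN3) divided
#'   by the larger of the two, for degree, closeness, eigenvector,
#'   betweenness and clustering, where each metric is normalised by its
#'   maximum over that network's own nodes (so F13-F17 lie in [-1, 1]).
#'
#' All divisions run through [safe_ratio()], so every output is finite even
#' for isolated query nodes; infinite shortest-path sentinels in F7 map
#' Inf/Inf to 1, finite/Inf to 0 and Inf/finite to the cap.
#'
#' @param triple A `psn_triple` from [build_triple()].
#' @param cap Ratio cap passed to [safe_ratio()].
#' @return One-row tibble with columns `F1`..`F17`.
#' @export
engineer_features <- function(triple, cap = 10) {
  q <- triple$query
  m1 <- compute_node_metrics(triple$cn1, q)
  met2 <- node_metrics(triple$cn2)
  met3 <- node_metrics(triple$cn3)
  m2 <- met2[met2$node == q, ]
  m3 <- met3[met3$node == q, ]
  if (!nrow(m2) || !nrow(m3) || !nrow(m1))
    abort("query node missing from a network.")
  diff_over_cn1 <- function(col)
    safe_ratio(m2[[col]] - m3[[col]], m1[[col]], cap)
  ratio23 <- function(col) safe_ratio(m2[[col]], m3[[col]], cap)
  norm_contrast <- function(col)
    safe_ratio(m2[[col]] - m3[[col]], max(m2[[col]], m3[[col]]), cap)
  tibble(
    F1 = diff_over_cn1("degree"),
    F2 = diff_over_cn1("weighted_degree"),
    F3 = diff_over_cn1("closeness"),
    F4 = diff_over_cn1("eigenvector"),
    F5 = diff_over_cn1("betweenness"),
    F6 = diff_over_cn1("clustering"),
    F7 = msp_ratio(m2$min_shortest_path, m3$min_shortest_path, cap),
    F8 = ratio23("two_hop"),
    F9 = ratio23("degree"),
    F10 = ratio23("closeness"),
    F11 = ratio23("eigenvector"),
    F12 = ratio23("betweenness"),
    F13 = norm_contrast("norm_degree"),
    F14 = norm_contrast("norm_closeness"),
    F15 = norm_contrast("norm_eigenvector"),
    F16 = norm_contrast("norm_betweenness"),
    F17 = norm_contrast("norm_clustering"))
}

#' Engineer features for every record of a table
#'
#' Builds the CN1/CN2/CN3 triple per record (each record in turn acting as
#' the query, with its own labelled copy excluded when it belongs to the
#' training set) and evaluates the 17 contrast features. Distances are
#' computed once for the training block and reused across queries.
#'
#' @param data Preprocessed records to featurise (may be the training table
#'   itself, or held-out records).
#' @param training Preprocessed training tibble with `outcome`; both tables
#'   must come from the same fitted preprocessing pipeline.
#' @param outcome Outcome column name.
#' @param tau_factor Distance-threshold multiplier.
#' @param cap Ratio cap.
#' @param self Set `TRUE` when `data` *is* the training table, so record i
#'   is excluded from its own networks (no leakage).
#' @param size_limit Community-partitioning node threshold, see
#'   [partition_communities()].
#' @param id_cols Identifier columns excluded from the geometry.
#' @return Tibble with `nrow(data)` rows and columns `F1`..`F17`.
#' @export
engineer_table <- function(data, training, outcome = "outcome",
                           tau_factor = 0.7, cap = 10, self = FALSE,
                           size_limit = 2000,
                           id_cols = c("couple_id", "cycle")) {
  feats <- setdiff(names(training), c(outcome, id_cols))
  y <- training[[outcome]]
  if (length(unique(y)) < 2) abort("both classes must be present in training.")
  Xt <- as.matrix(training[feats])
  Dt <- as.matrix(dist(Xt))
  Xq <- as.matrix(data[, feats, drop = FALSE])
  rows <- lapply(seq_len(nrow(Xq)), function(i) {
    if (self) {
      keep <- setdiff(seq_len(nrow(Xt)), i)
      if (length(unique(y[keep])) < 2)
        abort("excluding a record left a single-class training set.")
      dq <- Dt[i, keep]
      D <- rbind(c(0, dq), cbind(dq, Dt[keep, keep, drop = FALSE]))
      yy <- y[keep]
    } else {
      dq <- sqrt(colSums((t(Xt) - Xq[i, ])^2))
      D <- rbind(c(0, dq), cbind(dq, Dt))
      yy <- y
    }
    ids <- c("q", paste0("r", seq_len(ncol(D) - 1)))
    dimnames(D) <- list(ids, ids)
    triple <- triple_from_dist(D, yy, tau_factor)
    if (igraph::vcount(triple$cn1$graph) > size_limit) {
      triple$cn1 <- partition_communities(triple$cn1, size_limit)
      triple$cn2 <- partition_communities(triple$cn2, size_limit)
      triple$cn3 <- partition_communities(triple$cn3, size_limit)
      triple <- restrict_to_query_community(triple)
    }
    engineer_features(triple, cap)
  })
  dplyr::bind_rows(rows)
}

# keep only the query's community in each network of a triple
restrict_to_query_community <- function(triple) {
  for (nm in c("cn1", "cn2", "cn3")) {
    net <- triple[[nm]]
    if (is.null(net$community)) next
    keep <- names(net$community)[net$community == net$community[[triple$query]]]
    net$graph <- igraph::induced_subgraph(net$graph, keep)
    net$nodes <- keep
    net$community <- NULL
    triple[[nm]] <- net
  }
  triple
}

#' Write an engineered feature matrix to CSV
#' @param features Tibble of engineered features (`F1`..`F17`).
#' @param path Output path.
#' @param ids Optional record identifiers prepended as a column.
#' @export
write_features_csv <- function(features, path, ids = NULL) {
  if (!is.null(ids)) features <- dplyr::bind_cols(tibble(id = ids), features)
  readr::write_csv(features, path)
  invisible(path)
}
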