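# Binary-graph metrics: the three global characteristics (global efficiency,
# connection cost, mean clustering coefficient) and three nodal
# characteristics (degree, clustering coefficient, nodal efficiency).
# Distances are unweighted shortest-path hop counts (breadth-first search);
# 1/L for a disconnected pair contributes 0 (the limit of an infinite path).

as_adjacency <- function(g) {
  a <- unclass(g)
  a <- as.matrix(a)
  if (nrow(a) != ncol(a)) abort("adjacency must be square")
  if (any(a != 0 & a != 1)) abort("adjacency must be 0/1")
  if (any(a != t(a))) abort("adjacency must be symmetric (undirected graph)")
  if (any(diag(a) != 0)) abort("adjacency must have zero diagonal")
  a
}

#' Shortest-path hop counts between all node pairs
#'
#' Breadth-first search from every node of an undirected binary graph.
#'
#' @param g A `"binary_graph"` or symmetric 0/1 adjacency matrix.
#' @return An N x N matrix of hop counts, `0` on the diagonal and `Inf` for
#'   disconnected pairs.
#' @export
shortest_path_lengths <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  nb <- apply(a, 1, function(row) which(row == 1L), simplify = FALSE)
  out <- matrix(Inf, n, n, dimnames = dimnames(a))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(nb[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    out[s, ] <- dist
  }
  out
}

#' Global efficiency
#'
#' Mean of `1 / L_ij` over all ordered pairs of distinct nodes, where `L` is
#' the shortest-path hop count; 1 on a complete graph, 0 on an empty one.
#'
#' @inheritParams shortest_path_lengths
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) abort("need at least 2 nodes")
  l <- shortest_path_lengths(a)
  inv <- 1 / l
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Connection cost (edge density)
#'
#' Sum of nodal degrees over `N (N - 1)`; equals `2 E / (N (N - 1))`, the
#' fraction of possible edges present.
#'
#' @inheritParams shortest_path_lengths
#' @return A number in `[0, 1]`.
#' @export
connection_cost <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) abort("need at least 2 nodes")
  sum(a) / (n * (n - 1))
}

#' Nodal degree
#'
#' Number of links connected to each node.
#'
#' @inheritParams shortest_path_lengths
#' @return Integer vector of length N.
#' @export
nodal_degree <- function(g) {
  a <- as_adjacency(g)
  as.integer(rowSums(a))
}

#' Nodal clustering coefficient
#'
#' `C_i = e_i / (K_i (K_i - 1) / 2)` where `e_i` counts edges among node i's
#' neighbours; defined as 0 when `K_i < 2` (the formula is 0/0 there).
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector in `[0, 1]`.
#' @export
nodal_clustering <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  k <- rowSums(a)
  vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(a[i, ] == 1L)
    e_i <- sum(a[nb, nb]) / 2
    e_i / (k[i] * (k[i] - 1) / 2)
  }, numeric(1))
}

#' Mean clustering coefficient
#'
#' Arithmetic mean of the nodal clustering coefficients over all N nodes
#' (nodes of degree < 2 count as 0). Set `eligible_only = TRUE` to average
#' only over nodes with degree >= 2.
#'
#' @inheritParams shortest_path_lengths
#' @param eligible_only Average over degree >= 2 nodes only (default FALSE).
#' @return A number in `[0, 1]` (0 for a graph with no eligible node).
#' @export
mean_clustering <- function(g, eligible_only = FALSE) {
  a <- as_adjacency(g)
  ci <- nodal_clustering(a)
  if (eligible_only) {
    keep <- rowSums(a) >= 2
    if (!any(keep)) return(0)
    return(mean(ci[keep]))
  }
  mean(ci)
}

#' Nodal efficiency
#'
#' `E_i`: mean of `1 / L_ij` over all other nodes j; disconnected targets
#' contribute 0. Measures how well a node integrates with the rest of the
#' graph.
#'
#' @inheritParams shortest_path_lengths
#' @return Numeric vector in `[0, 1]`.
#' @export
nodal_efficiency <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a)
  if (n < 2) abort("need at least 2 nodes")
  l <- shortest_path_lengths(a)
  inv <- 1 / l
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' All six graph metrics of one binary graph, tidily
#'
#' @inheritParams shortest_path_lengths
#' @param node_names Optional node labels (defaults to adjacency dimnames or
#'   node numbers).
#' @return A tibble with columns `metric`, `node` (`"global"` for the three
#'   network-level characteristics) and `value`.
#' @export
graph_metrics <- function(g, node_names = NULL) {
  a <- as_adjacency(g)
  n <- nrow(a)
  nodes <- node_names %||% rownames(a) %||% as.character(seq_len(n))
  dplyr::bind_rows(
    tibble(metric = c("global_efficiency", "connection_cost", "mean_clustering"),
           node = "global",
           value = c(global_efficiency(a), connection_cost(a), mean_clustering(a))),
    tibble(metric = "degree", node = nodes, value = as.numeric(nodal_degree(a))),
    tibble(metric = "clustering", node = nodes, value = nodal_clustering(a)),
    tibble(metric = "efficiency", node = nodes, value = nodal_efficiency(a))
  )
}

#' Graph metrics across a threshold grid
#'
#' Binarizes the connectivity matrix at every threshold and computes all six
#' metrics, returning one tidy table.
#'
#' @param conn A `"connectivity"` object or correlation matrix.
#' @param thresholds Numeric vector of thresholds (default [threshold_grid()]).
#' @param abs_threshold Passed to [binarize()].
#' @return A tibble with columns `threshold`, `metric`, `node`, `value`.
#' @export
metrics_over_thresholds <- function(conn, thresholds = threshold_grid(),
                                    abs_threshold = FALSE) {
  purrr::map_dfr(thresholds, function(t) {
    m <- graph_metrics(binarize(conn, t, abs_threshold))
    dplyr::mutate(m, threshold = t, .before = 1)
  })
}
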