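test_that("shortest paths match enumeration on canonical graphs", {
  k4 <- complete_graph(4)
  d <- shortest_path_lengths(k4)
  expect_equal(d[upper.tri(d)], rep(1, 6))
  expect_equal(diag(d), rep(0, 4))

  ring5 <- ring_graph(5)
  d5 <- shortest_path_lengths(ring5)
  expect_equal(sort(d5[1, -1]), c(1, 1, 2, 2))  # per-node ring distances

  two_edges <- make_graph(list(c(1, 2), c(3, 4)), 4)
  dte <- shortest_path_lengths(two_edges)
  expect_true(all(is.infinite(dte[1:2, 3:4])))
  expect_equal(dte[1, 2], 1)
})

test_that("closed-form metric values are reproduced", {
  k4 <- complete_graph(4)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(connection_cost(k4), 1)
  expect_equal(mean_clustering(k4), 1)

  star5 <- star_graph(5)
  expect_equal(global_efficiency(star5), 0.7)
  expect_equal(connection_cost(star5), 0.4)
  expect_equal(nodal_degree(star5), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(nodal_efficiency(star5)[1], 1.0)        # centre
  expect_equal(nodal_efficiency(star5)[2], 0.625)      # leaf
  expect_equal(nodal_clustering(star5), rep(0, 5))     # no triangles

  tp <- triangle_pendant()
  expect_equal(nodal_clustering(tp), c(1, 1, 1 / 3, 0))
  expect_equal(mean_clustering(tp), 7 / 12)
  expect_equal(mean_clustering(tp, eligible_only = TRUE), mean(c(1, 1, 1 / 3)))

  empty <- matrix(0L, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  expect_equal(connection_cost(empty), 0)
  expect_equal(mean_clustering(empty), 0)
  expect_equal(nodal_efficiency(empty), rep(0, 4))     # isolated nodes

  ring6 <- ring_graph(6)
  expect_equal(nodal_degree(ring6), rep(2L, 6))
})

test_that("degrees satisfy the handshake lemma on random graphs", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_er_graph(sample(4:12, 1), runif(1, 0.2, 0.8))
    expect_equal(sum(nodal_degree(a)), sum(a))         # = 2 x edge count
  }
})

test_that("all metrics agree exactly with the brute-force oracle", {
  set.seed(33)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    a <- random_er_graph(n, sample(c(0.2, 0.5, 0.8), 1))
    expect_identical(shortest_path_lengths(a), oracle_distances(a),
                     info = paste("graph", i))
    expect_equal(global_efficiency(a), oracle_global_efficiency(a))
    expect_equal(connection_cost(a), oracle_cost(a))
    expect_equal(nodal_degree(a), oracle_degree(a))
    expect_equal(nodal_clustering(a), oracle_clustering(a))
    expect_equal(nodal_efficiency(a), oracle_nodal_efficiency(a))
    expect_equal(mean_clustering(a), mean(oracle_clustering(a)))
    # range invariants
    expect_true(all(nodal_efficiency(a) >= 0 & nodal_efficiency(a) <= 1))
    expect_true(all(nodal_clustering(a) >= 0 & nodal_clustering(a) <= 1))
  }
})

test_that("metrics agree with igraph on a random graph", {
  set.seed(8)
  a <- random_er_graph(12, 0.4)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  expect_equal(nodal_degree(a), unname(igraph::degree(g)))
  expect_equal(global_efficiency(a), igraph::global_efficiency(g))
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  # igraph returns NaN->0 handling via isolates; degree-1 nodes give NaN
  ci[is.na(ci)] <- 0
  expect_equal(nodal_clustering(a), unname(ci))
})

test_that("metrics are monotone along the threshold grid where theory says so", {
  set.seed(12)
  conn <- correlation_matrix(matrix(rnorm(80 * 12), 80, 12))
  grid <- threshold_grid()
  m <- metrics_over_thresholds(conn, grid)
  expect_equal(nrow(m), length(grid) * (3 + 3 * 12))

  glob <- dplyr::filter(m, node == "global")
  for (met in c("global_efficiency", "connection_cost")) {
    v <- dplyr::arrange(dplyr::filter(glob, metric == met), threshold)$value
    expect_true(all(diff(v) <= 1e-12), info = met)
  }
  for (met in c("degree", "efficiency")) {
    wide <- m |>
      dplyr::filter(metric == met) |>
      tidyr::pivot_wider(id_cols = "threshold", names_from = "node",
                         values_from = "value") |>
      dplyr::arrange(threshold)
    expect_true(all(apply(wide[, -1], 2, function(v) all(diff(v) <= 1e-12))),
                info = met)
  }
})
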