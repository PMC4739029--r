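# Small graph constructors and an independent brute-force oracle for the six
# graph metrics (Floyd-Warshall distances, exhaustive triple enumeration for
# clustering). The oracle shares no code with the package implementation.

make_graph <- function(edges, n) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

star_graph <- function(n) make_graph(lapply(2:n, function(i) c(1, i)), n)

ring_graph <- function(n) {
  make_graph(c(lapply(seq_len(n - 1), function(i) c(i, i + 1)), list(c(n, 1))), n)
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

triangle_pendant <- function() {
  # triangle 1-2-3 plus a pendant node 4 attached to node 3
  make_graph(list(c(1, 2), c(1, 3), c(2, 3), c(3, 4)), 4)
}

random_er_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(runif(sum(up)) < p)
  a + t(a)
}

# --- brute-force oracle ------------------------------------------------

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracle_cost <- function(a) sum(a) / (nrow(a) * (nrow(a) - 1))

oracle_degree <- function(a) as.integer(rowSums(a))

oracle_clustering <- function(a) {
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    k <- sum(a[i, ])
    if (k < 2) return(0)
    e_i <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j < l && a[i, j] == 1 && a[i, l] == 1 && a[j, l] == 1) e_i <- e_i + 1
      }
    }
    e_i / (k * (k - 1) / 2)
  })
}

oracle_nodal_efficiency <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  sapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(n)) {
      if (j != i && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
    tot / (n - 1)
  })
}
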