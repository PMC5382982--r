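# Independent brute-force implementations of every graph measure, written as
# direct transcriptions of the definitions (explicit loops, no shared code
# with the package internals). They serve as oracles for equivalence tests.

bf_degree <- function(adj) {
  n <- nrow(adj)
  k <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (adj[i, j] == 1) k[i] <- k[i] + 1L
  }
  k
}

bf_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) t_i <- t_i + 1L
      }
    }
    cc[i] <- 2 * t_i / (k * (k - 1))
  }
  cc
}

bf_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_efficiency <- function(adj) {
  d <- bf_floyd_warshall(adj)
  n <- nrow(adj)
  e <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    }
    e[i] <- s / (n - 1)
  }
  list(nodal = e, global = mean(e))
}

bf_char_path_length <- function(adj) {
  d <- bf_floyd_warshall(adj)
  vals <- c()
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) vals <- c(vals, d[i, j])
    }
  }
  mean(vals)
}

# Newman modularity of a given partition, straight from the definition:
# Q = sum_c (e_cc - a_c^2) with e_cc the within-module edge fraction and
# a_c the fraction of edge ends in module c.
bf_modularity_q <- function(adj, membership) {
  m <- sum(adj[upper.tri(adj)])
  mods <- unique(membership)
  q <- 0
  for (c in mods) {
    nodes <- which(membership == c)
    within <- sum(adj[nodes, nodes, drop = FALSE]) / 2
    ends <- sum(adj[nodes, , drop = FALSE])
    q <- q + within / m - (ends / (2 * m))^2
  }
  q
}

# All set partitions of 1..n via restricted growth strings (n <= 9 or so);
# used to find the exact maximal-Q partition by exhaustion.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxval) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxval + 1)) grow(c(prefix, v), max(maxval, v))
  }
  grow(1L, 1L)
  out
}

bf_max_modularity <- function(adj) {
  best <- -Inf
  for (p in all_partitions(nrow(adj))) {
    q <- bf_modularity_q(adj, p)
    if (q > best) best <- q
  }
  best
}

# Directly counted component extents for NBS cross-checks.
bf_node_incidence <- function(edge_list, n_nodes) {
  counts <- integer(n_nodes)
  for (r in seq_len(nrow(edge_list))) {
    counts[edge_list[r, 1]] <- counts[edge_list[r, 1]] + 1L
    counts[edge_list[r, 2]] <- counts[edge_list[r, 2]] + 1L
  }
  counts
}

# Small fixed graphs used across tests.
graph_path3 <- function() {
  binary_graph(matrix(c(0, 1, 0,
                        1, 0, 1,
                        0, 1, 0), 3, 3, byrow = TRUE))
}

graph_complete <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  binary_graph(adj)
}

graph_two_cliques <- function(size = 10) {
  n <- 2 * size
  adj <- matrix(0L, n, n)
  adj[seq_len(size), seq_len(size)] <- 1L
  adj[(size + 1):n, (size + 1):n] <- 1L
  diag(adj) <- 0L
  binary_graph(adj)
}
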