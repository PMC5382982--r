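test_that("closed-form metric values on elementary graphs", {
  k5 <- graph_complete(5)
  expect_identical(node_degree(k5), rep(4L, 5))
  expect_equal(clustering_coefficient(k5), rep(1, 5))
  pm <- path_metrics(k5)
  expect_equal(pm$char_path_length, 1)
  expect_equal(pm$global_efficiency, 1)
  expect_equal(pm$nodal_efficiency, rep(1, 5))

  star <- binary_graph(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                             c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_identical(node_degree(star), c(3L, 1L, 1L, 1L))

  p3 <- graph_path3()
  expect_equal(clustering_coefficient(p3), rep(0, 3))
  pm3 <- path_metrics(p3)
  expect_equal(pm3$char_path_length, 4 / 3)
  expect_equal(pm3$global_efficiency, 5 / 6)
  expect_equal(pm3$nodal_efficiency, c(3 / 4, 1, 3 / 4))
  d3 <- shortest_path_matrix(p3)
  expect_equal(d3[1, 3], 2)

  # K4 minus the edge (3,4): triangles enumerated by hand
  k4m <- graph_complete(4)$adjacency
  k4m[3, 4] <- k4m[4, 3] <- 0L
  expect_equal(clustering_coefficient(binary_graph(k4m)),
               c(2 / 3, 2 / 3, 1, 1))
})

test_that("disconnected graphs use reachable pairs and the 1/Inf = 0 convention", {
  two_edges <- binary_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                  c(0, 0, 0, 1), c(0, 0, 1, 0)))
  pm <- path_metrics(two_edges)
  expect_equal(pm$global_efficiency, 1 / 3)
  expect_equal(pm$char_path_length, 1)
  empty <- binary_graph(matrix(0, 3, 3))
  expect_error(path_metrics(empty), "no edges")
})

test_that("metrics match brute-force oracles on random graphs", {
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    m <- sample.int(n * (n - 1) / 2, 1)
    g <- make_random_graph(n, m)
    adj <- g$adjacency
    expect_identical(node_degree(g), bf_degree(adj))
    expect_equal(clustering_coefficient(g), bf_clustering(adj))
    expect_equal(shortest_path_matrix(g), bf_floyd_warshall(adj))
    if (g$edge_count > 0) {
      eff <- bf_efficiency(adj)
      pm <- path_metrics(g)
      expect_equal(pm$nodal_efficiency, eff$nodal)
      expect_equal(pm$global_efficiency, eff$global)
      expect_equal(pm$char_path_length, bf_char_path_length(adj))
      # handshake lemma
      expect_identical(sum(node_degree(g)), 2L * g$edge_count)
      # Q of the greedy partition agrees with the definition-level formula
      mod <- greedy_modularity(g)
      expect_equal(mod$modularity, bf_modularity_q(adj, mod$membership))
    }
  }
})

test_that("greedy modularity finds planted structure and respects the exhaustive bound", {
  two <- graph_two_cliques(10)
  mod <- greedy_modularity(two)
  expect_identical(mod$n_modules, 2L)
  expect_equal(mod$modularity, 0.5)
  expect_identical(length(unique(mod$membership[1:10])), 1L)

  # any single-module partition of a complete graph has Q = 0
  expect_equal(bf_modularity_q(graph_complete(6)$adjacency, rep(1, 6)), 0)

  set.seed(13)
  for (rep in 1:10) {
    g <- make_random_graph(7, sample(3:15, 1))
    if (g$edge_count == 0) next
    mod <- greedy_modularity(g)
    expect_lte(mod$modularity, bf_max_modularity(g$adjacency) + 1e-12)
  }

  # planted two-clique partition recovered exactly at small n
  small <- graph_two_cliques(4)
  mod4 <- greedy_modularity(small)
  expect_equal(mod4$modularity, bf_max_modularity(small$adjacency))
  expect_identical(mod4$n_modules, 2L)

  expect_error(greedy_modularity(binary_graph(matrix(0, 3, 3))), "empty")
})

test_that("random references preserve the degree multiset, always", {
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(8:25, 1)
    g <- make_random_graph(n, sample(5:20, 1))
    if (g$edge_count < 2) next
    r <- random_reference(g)
    expect_identical(sort(node_degree(r)), sort(node_degree(g)))
    expect_identical(node_degree(r), node_degree(g)) # per-node, not just multiset
    expect_identical(diag(r$adjacency), rep(0L, n))
  }
})

test_that("rewiring is deterministic given a seed and cannot alter a triangle", {
  g <- make_random_graph(20, 40, seed = 1)
  a <- random_reference(g, seed = 99)
  b <- random_reference(g, seed = 99)
  expect_identical(a$adjacency, b$adjacency)
  k3 <- graph_complete(3)
  expect_identical(random_reference(k3, seed = 1)$adjacency, k3$adjacency)
  expect_error(random_reference(binary_graph(matrix(0, 3, 3))), "2 edges")
})

test_that("small-world index separates lattices from random graphs", {
  lat <- make_lattice_graph(100, 10)
  sw <- small_world_profile(lat, n_rand = 20, seed = 21)
  expect_gt(sw$small_world, 2)

  er <- make_random_graph(100, 500, seed = 22)
  sw_er <- small_world_profile(er, n_rand = 20, seed = 23)
  expect_gt(sw_er$small_world, 0.8)
  expect_lt(sw_er$small_world, 1.2)
  # an ER graph is (statistically) its own randomization
  expect_equal(sw_er$c_norm, 1, tolerance = 0.2)
  expect_equal(sw_er$l_norm, 1, tolerance = 0.2)

  kc <- graph_complete(8)
  sw_k <- small_world_profile(kc, n_rand = 3, seed = 24)
  expect_equal(sw_k$small_world, 1) # rewiring cannot change K_n
})

test_that("AUC integration is exact for constant and linear curves", {
  grid <- sparsity_grid()
  expect_equal(auc_over_sparsity(rep(3, 10), grid), 0.45 * 3)
  expect_equal(auc_over_sparsity(grid, grid), (0.5^2 - 0.05^2) / 2)
  expect_identical(auc_over_sparsity(rep(0, 10), grid), 0)
  expect_error(auc_over_sparsity(1, grid = 0.3), "two grid points")
  expect_error(auc_over_sparsity(1:3, grid = c(0.1, 0.2)), "lengths differ")
})

test_that("subject profiles are reproducible and internally consistent", {
  set.seed(15)
  coh <- generate_cohort(
    cohort_spec(n_lesion = 1, n_sham = 1, n_nodes = 40, n_hemisphere = 20,
                n_volumes = 300, n_modules = 4, drift_amplitude = 0,
                spike_fraction = 0, seed = 16))
  r <- pearson_matrix(coh$subjects[[1]]$ts)
  grid <- sparsity_grid(0.1, 0.5, 0.1)
  p1 <- subject_profile(r, grid, n_rand = 5, seed = 30)
  p2 <- subject_profile(r, grid, n_rand = 5, seed = 30)
  expect_identical(p1, p2)

  # identical matrices give identical profiles
  r2 <- r
  attr(r2, "subject_id") <- attr(r, "subject_id")
  p3 <- subject_profile(r2, grid, n_rand = 5, seed = 30)
  expect_identical(p1, p3)

  # degree sums match twice the imposed edge count at every threshold
  npairs <- 40 * 39 / 2
  for (sp in grid) {
    k <- p1$nodal$degree[p1$nodal$sparsity == sp]
    expect_identical(sum(k), 2L * as.integer(round(sp * npairs)))
  }
  # E_glob equals the mean nodal efficiency
  for (sp in grid) {
    e <- p1$nodal$efficiency[p1$nodal$sparsity == sp]
    eg <- p1$global$global_efficiency[p1$global$sparsity == sp]
    expect_equal(mean(e), eg)
  }
  # modularity of a modular subject decreases as the graph densifies
  q <- p1$global$modularity
  expect_gt(q[1], q[length(q)])

  # AUC of clustering (bounded by 1) lies within the grid width
  cl_auc <- p1$auc$auc[p1$auc$measure == "clustering"]
  expect_true(all(cl_auc >= 0 & cl_auc <= 0.4 + 1e-12))
})

test_that("neighbourhood local efficiency behaves on canonical graphs", {
  expect_equal(local_efficiency(graph_complete(5)), rep(1, 5))
  expect_equal(local_efficiency(graph_path3()), rep(0, 3))
})
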