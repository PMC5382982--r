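#' Node degree
#'
#' Number of edges incident to each node; the basic measure of a node's
#' influence. Degrees always sum to twice the edge count.
#'
#' @param g A [binary_graph()].
#' @return Integer vector of length `n_nodes`.
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  as.integer(rowSums(g$adjacency))
}

#' Local clustering coefficient
#'
#' For node `i` with degree `k_i` and `t_i` triangles through it,
#' `c_i = 2 t_i / (k_i (k_i - 1))`: the fraction of neighbour pairs that are
#' themselves connected, a measure of local segregation. Nodes with degree
#' below 2 get `c_i = 0`. The network mean of this vector is the global
#' clustering level.
#'
#' @param g A [binary_graph()].
#' @return Numeric vector in `[0, 1]`, length `n_nodes`.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  cc <- igraph::transitivity(as_igraph(g), type = "local", isolates = "zero")
  as.numeric(cc)
}

#' All-pairs shortest-path (hop) distances
#'
#' Breadth-first-search distances between every pair of nodes; `Inf` marks
#' unreachable pairs, `0` the diagonal.
#'
#' @param g A [binary_graph()].
#' @return Symmetric numeric matrix of hop counts.
#' @export
shortest_path_matrix <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  dimnames(d) <- NULL
  d
}

#' Path length and efficiency measures
#'
#' Integration measures from the shortest-path structure:
#' * nodal efficiency `e_i = mean_{j != i} 1/d(i, j)` with the convention
#'   `1/Inf = 0`, so disconnection lowers efficiency instead of breaking it;
#' * global efficiency `E_glob = mean_i e_i`, the network's capacity for
#'   parallel information transfer (the inverse-path-length counterpart);
#' * characteristic path length `L`, the mean distance over *reachable*
#'   ordered node pairs, which stays finite on disconnected graphs.
#'
#' A graph with zero edges has no defined path length and is rejected.
#'
#' @param g A [binary_graph()].
#' @return List with `char_path_length`, `global_efficiency` and the nodal
#'   efficiency vector `nodal_efficiency`.
#' @export
path_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$edge_count == 0L) stopf("path length undefined: graph has no edges")
  d <- shortest_path_matrix(g)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  e <- rowSums(inv) / (n - 1)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  list(char_path_length = mean(finite),
       global_efficiency = mean(e),
       nodal_efficiency = e)
}

#' Neighbourhood-subgraph local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbours (the node itself excluded); 0 for nodes with fewer than two
#' neighbours. This is the classic "local efficiency" variant; note that
#' nodal integration analyses in this package default to the whole-network
#' nodal efficiency of [path_metrics()] instead.
#'
#' @param g A [binary_graph()].
#' @return Numeric vector in `[0, 1]`, length `n_nodes`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  vapply(seq_len(g$n_nodes), function(i) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2L) return(0)
    sub <- binary_graph(adj[nb, nb, drop = FALSE])
    if (sub$edge_count == 0L) return(0)
    path_metrics(sub)$global_efficiency
  }, numeric(1))
}

#' Degree-preserving random reference network
#'
#' Randomizes a graph by repeated double-edge swaps (pick edges (a,b) and
#' (c,d), rewire to (a,d) and (c,b)), which preserve every node's degree
#' exactly while destroying all higher-order structure. Swaps that would
#' create self-loops or duplicate edges are rejected and retried, so the
#' result is always a simple graph with the same degree multiset. These
#' references provide the null clustering and path length against which
#' small-worldness is normalized.
#'
#' @param g A [binary_graph()] with at least 2 edges.
#' @param n_swaps_per_edge Attempted swaps per edge (default 10), enough to
#'   decorrelate the edge set from the original.
#' @param seed Optional seed; the caller's RNG state is left untouched when
#'   supplied.
#' @return A [binary_graph()] with the identical degree sequence.
#' @export
random_reference <- function(g, n_swaps_per_edge = 10L, seed = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$edge_count < 2L) stopf("need at least 2 edges to rewire")
  if (!is_count(n_swaps_per_edge, 1L)) {
    stopf("`n_swaps_per_edge` must be a positive count")
  }
  ig <- as_igraph(g)
  rewired <- with_opt_seed(seed,
    igraph::rewire(ig, igraph::keeping_degseq(
      loops = FALSE, niter = n_swaps_per_edge * g$edge_count)))
  adj <- as.matrix(igraph::as_adjacency_matrix(rewired, sparse = FALSE))
  binary_graph(adj, sparsity = g$sparsity)
}

#' Small-world profile of a graph
#'
#' Compares a graph's clustering and path length to the means over `n_rand`
#' independent degree-preserving random references:
#' `c_norm = C / C_rand`, `l_norm = L / L_rand`, and the small-world index
#' `S = c_norm / l_norm`. Small-world networks (high segregation at near-
#' random path length) give `S` well above 1; an Erdos-Renyi graph gives
#' `S` near 1.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @param n_rand Number of random references to average (default 100).
#' @param seed Optional seed controlling the randomization.
#' @return List with `c_norm`, `l_norm`, `small_world`, plus the raw
#'   `mean_clustering`, `char_path_length`, `c_rand`, `l_rand`.
#' @export
small_world_profile <- function(g, n_rand = 100L, seed = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  if (!is_count(n_rand, 1L)) stopf("`n_rand` must be a positive count")
  c_obs <- mean(clustering_coefficient(g))
  l_obs <- path_metrics(g)$char_path_length
  refs <- with_opt_seed(seed, lapply(seq_len(n_rand), function(i) {
    r <- random_reference(g)
    c(mean(clustering_coefficient(r)), path_metrics(r)$char_path_length)
  }))
  refs <- do.call(rbind, refs)
  c_rand <- mean(refs[, 1])
  l_rand <- mean(refs[, 2])
  if (c_rand == 0) {
    stopf("degenerate graph: random references have zero clustering, small-world index undefined")
  }
  c_norm <- c_obs / c_rand
  l_norm <- l_obs / l_rand
  list(c_norm = c_norm, l_norm = l_norm, small_world = c_norm / l_norm,
       mean_clustering = c_obs, char_path_length = l_obs,
       c_rand = c_rand, l_rand = l_rand)
}

#' Greedy modularity optimization
#'
#' Agglomerative greedy maximization of Newman modularity
#' `Q = sum_c (e_cc - a_c^2)`, where `e_cc` is the fraction of edges inside
#' community `c` and `a_c` the fraction of edge ends attached to `c`.
#' Starting from singletons, the pair of communities whose merge most
#' increases `Q` is merged repeatedly; the partition with maximal `Q` along
#' the merge path is returned. Isolated nodes remain singleton modules and
#' count toward `n_modules`.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @return List with `membership` (integer module id per node), `modularity`
#'   (`Q`) and `n_modules`.
#' @export
greedy_modularity <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$edge_count == 0L) stopf("modularity undefined on an empty graph")
  fc <- igraph::cluster_fast_greedy(as_igraph(g))
  memb <- as.integer(igraph::membership(fc))
  list(membership = memb,
       modularity = igraph::modularity(as_igraph(g), memb),
       n_modules = length(unique(memb)))
}

#' Area under a metric curve over the sparsity grid
#'
#' Composite trapezoidal integral of a metric across sparsity thresholds,
#' giving a single threshold-independent summary per node (or per network).
#' The trapezoid rule is exact for the piecewise-linear curve the grid
#' defines. For the default grid (0.05 to 0.5) a metric bounded by `[0, B]`
#' yields an AUC in `[0, 0.45 B]`.
#'
#' @param values Metric values, one per grid point.
#' @param grid Strictly increasing sparsity thresholds (>= 2 points).
#' @return The definite integral (units: metric x sparsity).
#' @export
auc_over_sparsity <- function(values, grid = sparsity_grid()) {
  if (length(grid) < 2L) stopf("AUC needs at least two grid points")
  if (length(values) != length(grid)) {
    stopf("`values` (%d) and `grid` (%d) lengths differ",
          length(values), length(grid))
  }
  if (any(diff(grid) <= 0)) stopf("grid must be strictly increasing")
  pracma::trapz(grid, values)
}

#' Full metric profile of one subject
#'
#' Thresholds a connectivity matrix across the sparsity grid and assembles
#' every topology measure used in group analysis: per-threshold global
#' metrics (mean clustering, characteristic path length, global efficiency,
#' modularity and module count, and — when `n_rand > 0` — normalized
#' clustering, normalized path length and the small-world index), per-node
#' metrics (degree, clustering, nodal efficiency), and the per-node AUC of
#' each nodal metric over the grid. Deterministic given `seed`.
#'
#' @param r Correlation matrix from [pearson_matrix()].
#' @param grid Sparsity thresholds (default [sparsity_grid()]).
#' @param n_rand Random references per threshold for normalization; 0 skips
#'   normalization (the random-network columns are then `NA`).
#' @param seed Optional seed for the random references.
#' @param edge_rank Passed to [threshold_by_sparsity()].
#' @return List of three data frames: `global` (one row per threshold),
#'   `nodal` (one row per threshold x node) and `auc` (one row per node x
#'   measure), each carrying the subject id.
#' @export
subject_profile <- function(r, grid = sparsity_grid(), n_rand = 100L,
                            seed = NULL, edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  subject_id <- attr(r, "subject_id")
  if (is.null(subject_id)) subject_id <- NA_character_
  graphs <- threshold_series(r, grid, edge_rank)
  n <- nrow(r)

  per_sp <- with_opt_seed(seed, lapply(graphs, function(g) {
    k <- node_degree(g)
    cc <- clustering_coefficient(g)
    pm <- path_metrics(g)
    q <- greedy_modularity(g)
    sw <- if (n_rand > 0) small_world_profile(g, n_rand = n_rand) else NULL
    list(
      global = data.frame(
        sparsity = g$sparsity,
        mean_clustering = mean(cc),
        char_path_length = pm$char_path_length,
        global_efficiency = pm$global_efficiency,
        modularity = q$modularity,
        n_modules = q$n_modules,
        c_norm = if (is.null(sw)) NA_real_ else sw$c_norm,
        l_norm = if (is.null(sw)) NA_real_ else sw$l_norm,
        small_world = if (is.null(sw)) NA_real_ else sw$small_world),
      nodal = data.frame(
        sparsity = g$sparsity, node = seq_len(n),
        degree = k, clustering = cc, efficiency = pm$nodal_efficiency))
  }))

  global <- do.call(rbind, lapply(per_sp, `[[`, "global"))
  nodal <- do.call(rbind, lapply(per_sp, `[[`, "nodal"))
  rownames(global) <- rownames(nodal) <- NULL

  auc <- do.call(rbind, lapply(c("degree", "clustering", "efficiency"),
    function(measure) {
      m <- matrix(nodal[[measure]], nrow = length(grid), ncol = n, byrow = TRUE)
      data.frame(node = seq_len(n), measure = measure,
                 auc = apply(m, 2, auc_over_sparsity, grid = grid))
    }))
  rownames(auc) <- NULL

  global$subject_id <- nodal$subject_id <- auc$subject_id <- subject_id
  list(global = global, nodal = nodal, auc = auc)
}
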