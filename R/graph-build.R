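#' Binary undirected graph at a given sparsity
#'
#' Thin container for an unweighted, undirected, self-loop-free adjacency
#' matrix together with the sparsity (fraction of possible edges present) it
#' was thresholded at. `edge_count` is derived from the adjacency.
#'
#' @param adjacency Square symmetric 0/1 matrix with zero diagonal.
#' @param sparsity Fraction of the `R(R-1)/2` possible edges present, in
#'   `[0, 1]`.
#' @return An object of class `binary_graph` with elements `adjacency`,
#'   `sparsity`, `edge_count` and `n_nodes`.
#' @export
binary_graph <- function(adjacency, sparsity = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stopf("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stopf("adjacency must be binary")
  if (any(diag(adjacency) != 0)) stopf("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stopf("adjacency must be symmetric")
  }
  storage.mode(adjacency) <- "integer"
  m <- sum(adjacency[upper.tri(adjacency)])
  if (is.null(sparsity)) sparsity <- m / (n * (n - 1) / 2)
  if (!is.numeric(sparsity) || sparsity < 0 || sparsity > 1) {
    stopf("sparsity must lie in [0, 1]")
  }
  structure(list(adjacency = adjacency, sparsity = as.numeric(sparsity),
                 edge_count = as.integer(m), n_nodes = as.integer(n)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %.3g)\n",
              x$n_nodes, x$edge_count, x$sparsity))
  invisible(x)
}

# igraph view of a binary_graph; the workhorse for path/community metrics.
as_igraph <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Pearson functional connectivity matrix
#'
#' Pairwise sample Pearson correlations across all ROI columns of a cleaned
#' time series, yielding the R x R functional connectivity matrix whose
#' off-diagonal entries define candidate edges. The diagonal is set to 1.
#'
#' @param ts An [roi_ts()] (only its `data` is used) or a plain
#'   volumes x ROIs numeric matrix.
#' @return A symmetric R x R correlation matrix with unit diagonal, ROI
#'   names as dimnames and the subject id in attribute `"subject_id"`.
#' @export
pearson_matrix <- function(ts) {
  data <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  if (nrow(data) < 3L) stopf("need at least 3 time points for correlation")
  sds <- apply(data, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stopf("constant ROI column(s), correlation undefined: %s",
          paste(bad, collapse = ","))
  }
  r <- cor(data)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  if (is.null(dimnames(r))) dimnames(r) <- list(roi_names(ncol(data)),
                                                roi_names(ncol(data)))
  attr(r, "subject_id") <- if (inherits(ts, "roi_ts")) ts$subject_id else NA_character_
  r
}

#' Sparsity grid constructor
#'
#' Strictly increasing sparsity thresholds within `(0, 1]`. The default
#' `0.05, 0.10, ..., 0.50` spans the range over which brain graphs remain
#' both connected enough to measure and sparse enough to be non-trivial.
#'
#' @param from,to,by Grid limits and step.
#' @return Numeric vector of thresholds.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.5, by = 0.05) {
  if (!(is.numeric(from) && is.numeric(to) && is.numeric(by) && by > 0)) {
    stopf("invalid sparsity grid: need numeric from/to and step > 0")
  }
  g <- seq(from, to, by = by)
  if (length(g) < 1L || any(g <= 0) || any(g > 1) || any(diff(g) <= 0)) {
    stopf("sparsity grid must be strictly increasing within (0, 1]")
  }
  g
}

#' Threshold a connectivity matrix at a fixed sparsity
#'
#' Retains exactly `K = round(sp * R(R-1)/2)` edges (rounding half away from
#' zero), chosen as the `K` strongest off-diagonal correlations, and returns
#' the corresponding unweighted undirected graph. Fixing the edge count
#' rather than the correlation cutoff equalizes wiring cost across subjects,
#' so topology comparisons are not confounded by overall correlation level.
#'
#' Edges are ranked by signed correlation by default (strongest positive
#' first); set `edge_rank = "absolute"` to let strong negative correlations
#' compete. Ties at the K-th rank are broken lexicographically by
#' `(i, j)` node index, making edge sets deterministic and nested across
#' increasing sparsities.
#'
#' @param r Symmetric correlation matrix (see [pearson_matrix()]).
#' @param sp Sparsity threshold in `(0, 1]`; must yield `K >= 1`.
#' @param edge_rank `"signed"` (default) or `"absolute"`.
#' @return A [binary_graph()] with exactly `K` edges.
#' @export
threshold_by_sparsity <- function(r, sp, edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  r <- as.matrix(r)
  n <- nrow(r)
  if (n != ncol(r)) stopf("correlation matrix must be square")
  if (!is.numeric(sp) || sp <= 0 || sp > 1) stopf("`sp` must lie in (0, 1]")
  npairs <- n * (n - 1) / 2
  k <- round_half_up(sp * npairs)
  if (k < 1) stopf("sparsity %.4g keeps zero of %d possible edges", sp, npairs)
  pairs <- upper_pairs(n)
  v <- r[pairs]
  key <- if (edge_rank == "signed") -v else -abs(v)
  ord <- order(key, pairs[, 1L], pairs[, 2L])
  keep <- pairs[ord[seq_len(k)], , drop = FALSE]
  adj <- matrix(0L, n, n)
  adj[keep] <- 1L
  adj <- adj + t(adj)
  binary_graph(adj, sparsity = sp)
}

#' Threshold a connectivity matrix over a sparsity grid
#'
#' One [binary_graph()] per grid value. With the deterministic tie-break of
#' [threshold_by_sparsity()], the edge set at a smaller sparsity is always a
#' subset of the edge set at a larger one.
#'
#' @inheritParams threshold_by_sparsity
#' @param grid Thresholds from [sparsity_grid()].
#' @return Named list of [binary_graph()] objects, one per grid value.
#' @export
threshold_series <- function(r, grid = sparsity_grid(),
                             edge_rank = c("signed", "absolute")) {
  edge_rank <- match.arg(edge_rank)
  if (length(grid) < 1L || any(grid <= 0) || any(grid > 1) ||
      any(diff(grid) <= 0)) {
    stopf("sparsity grid must be strictly increasing within (0, 1]")
  }
  out <- lapply(grid, function(sp) threshold_by_sparsity(r, sp, edge_rank))
  names(out) <- formatC(grid, format = "g")
  out
}
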