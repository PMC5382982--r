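#' Two-group study design
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param labels Group label per subject, `"lesion"` or `"sham"`; both
#'   groups must be non-empty.
#' @return A list of class `group_design` with `subject_ids`, `labels`,
#'   `n_lesion`, `n_sham`.
#' @export
group_design <- function(subject_ids, labels) {
  subject_ids <- as.character(subject_ids)
  labels <- as.character(labels)
  if (length(subject_ids) != length(labels)) {
    stopf("`subject_ids` and `labels` lengths differ")
  }
  if (!all(labels %in% c("lesion", "sham"))) {
    stopf("labels must be 'lesion' or 'sham'")
  }
  if (anyDuplicated(subject_ids)) stopf("duplicated subject ids")
  n_lesion <- sum(labels == "lesion")
  n_sham <- sum(labels == "sham")
  if (n_lesion < 1L || n_sham < 1L) stopf("both groups must be non-empty")
  structure(list(subject_ids = subject_ids, labels = labels,
                 n_lesion = n_lesion, n_sham = n_sham),
            class = "group_design")
}

# Pooled-variance (or Welch) two-sample t; returns t, df, p and the group
# means. Errors when both groups are constant (t undefined).
two_sample_t <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stopf("each group needs >= 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  diff <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    if (diff == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1,
                               mean_x = mean(x), mean_y = mean(y)))
    stopf("zero variance in both groups with unequal means: t undefined")
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- diff / se
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df),
       mean_x = mean(x), mean_y = mean(y))
}

#' Mixed group-by-sparsity ANOVA on a global metric
#'
#' Two-factor mixed-model ANOVA with group (lesion vs sham) as the
#' between-subject factor and sparsity threshold as the within-subject
#' (repeated) factor: the split-plot decomposition tests the group main
#' effect against between-subject variation and the sparsity main effect and
#' group x sparsity interaction against the within-subject residual. When a
#' main effect is present, per-threshold two-sample comparisons with
#' Bonferroni correction localize it.
#'
#' @param metric_table Data frame with columns `subject`, `group`,
#'   `sparsity`, `value`; every subject must have a value at every
#'   sparsity level.
#' @param var_equal Pooled-variance post hoc t-tests when `TRUE` (default).
#' @return List with `anova` (data frame: effect, df1, df2, F, p) and
#'   `posthoc` (data frame: sparsity, t, df, p, p_bonferroni).
#' @export
mixed_anova_global <- function(metric_table, var_equal = TRUE) {
  need <- c("subject", "group", "sparsity", "value")
  if (!all(need %in% names(metric_table))) {
    stopf("metric_table needs columns %s", paste(need, collapse = ", "))
  }
  df <- data.frame(subject = factor(metric_table$subject),
                   group = factor(metric_table$group),
                   sparsity = factor(metric_table$sparsity),
                   value = as.numeric(metric_table$value))
  counts <- table(df$subject, df$sparsity)
  if (any(counts != 1L)) stopf("every subject needs exactly one value per sparsity level")
  per_group <- rowSums(table(df$group, df$subject) > 0)
  if (any(per_group < 2L)) stopf("each group needs >= 2 subjects")

  n_sp <- nlevels(df$sparsity)
  if (n_sp > 1L) {
    fit <- aov(value ~ group * sparsity + Error(subject), data = df)
    sm <- summary(fit)
    between <- sm[["Error: subject"]][[1]]
    within <- sm[["Error: Within"]][[1]]
    pick <- function(tab, name) {
      i <- match(name, trimws(rownames(tab)))
      resid <- match("Residuals", trimws(rownames(tab)))
      data.frame(effect = name, df1 = tab$Df[i], df2 = tab$Df[resid],
                 F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
    }
    anova_tab <- rbind(pick(between, "group"),
                       pick(within, "sparsity"),
                       pick(within, "group:sparsity"))
  } else {
    # single sparsity level: the mixed design degenerates to a one-way
    # between-subject comparison (F = t^2)
    fit <- aov(value ~ group, data = df)
    tab <- summary(fit)[[1]]
    anova_tab <- data.frame(effect = "group", df1 = tab$Df[1],
                            df2 = tab$Df[2], F = tab$`F value`[1],
                            p = tab$`Pr(>F)`[1])
  }
  rownames(anova_tab) <- NULL

  posthoc <- do.call(rbind, lapply(levels(df$sparsity), function(sp) {
    sub <- df[df$sparsity == sp, ]
    tt <- two_sample_t(sub$value[sub$group == "lesion"],
                       sub$value[sub$group == "sham"], var_equal)
    data.frame(sparsity = as.numeric(sp), t = tt$t, df = tt$df, p = tt$p,
               p_bonferroni = min(1, tt$p * n_sp))
  }))
  rownames(posthoc) <- NULL
  list(anova = anova_tab, posthoc = posthoc)
}

#' Nodal AUC group comparison with FDR correction
#'
#' Two-sided two-sample t-test per node on a threshold-independent nodal
#' summary (typically the AUC of degree, clustering or nodal efficiency over
#' the sparsity grid), followed by Benjamini-Hochberg correction across all
#' nodes. Both the uncorrected (p < `alpha`) and FDR (q < `q`) significant
#' sets are flagged, with each node's direction of change in the lesion
#' group relative to sham.
#'
#' @param auc_matrix Subjects x nodes numeric matrix; row order must match
#'   `design$subject_ids`.
#' @param design A [group_design()].
#' @param q FDR level (default 0.05).
#' @param alpha Uncorrected significance level (default 0.05).
#' @param var_equal Pooled-variance t-tests when `TRUE` (default); Welch
#'   otherwise.
#' @return Data frame with one row per node: `node`, `t`, `df`, `p`,
#'   `q_value`, `direction` (`"increase"`/`"decrease"` in lesion vs sham),
#'   `sig_uncorrected`, `sig_fdr`.
#' @export
nodal_auc_ttests <- function(auc_matrix, design, q = 0.05, alpha = 0.05,
                             var_equal = TRUE) {
  stopifnot(inherits(design, "group_design"))
  auc_matrix <- as.matrix(auc_matrix)
  if (nrow(auc_matrix) != length(design$labels)) {
    stopf("auc_matrix has %d rows but the design lists %d subjects",
          nrow(auc_matrix), length(design$labels))
  }
  lesion <- design$labels == "lesion"
  res <- lapply(seq_len(ncol(auc_matrix)), function(j) {
    tt <- two_sample_t(auc_matrix[lesion, j], auc_matrix[!lesion, j],
                       var_equal)
    data.frame(node = j, t = tt$t, df = tt$df, p = tt$p,
               direction = if (tt$mean_x >= tt$mean_y) "increase" else "decrease")
  })
  res <- do.call(rbind, res)
  res$q_value <- p.adjust(res$p, method = "BH")
  res$sig_uncorrected <- res$p < alpha
  res$sig_fdr <- res$q_value < q
  res[, c("node", "t", "df", "p", "q_value", "direction",
          "sig_uncorrected", "sig_fdr")]
}

# Stack the upper triangles of per-subject connectivity matrices into a
# subjects x edges matrix; returns the matrix and the edge (i, j) pairs.
edge_value_matrix <- function(matrices) {
  n <- nrow(matrices[[1]])
  pairs <- upper_pairs(n)
  x <- t(vapply(matrices, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != n) stopf("matrices differ in size")
    m[pairs]
  }, numeric(nrow(pairs))))
  list(x = x, pairs = pairs, n_nodes = n)
}

# Edge-wise pooled-variance t-statistics (group1 - group2) for many
# relabelings at once. `assign1` is a logical matrix, relabelings x subjects,
# TRUE marking membership of group 1. Returns relabelings x edges.
edgewise_t_matrix <- function(x, x2, assign1, n1, n2) {
  p1 <- assign1 * 1
  s1 <- p1 %*% x
  ss1 <- p1 %*% x2
  tot <- matrix(colSums(x), nrow(s1), ncol(s1), byrow = TRUE)
  tot2 <- matrix(colSums(x2), nrow(s1), ncol(s1), byrow = TRUE)
  s2 <- tot - s1
  ss2 <- tot2 - ss1
  v1 <- (ss1 - s1^2 / n1) / (n1 - 1)
  v2 <- (ss2 - s2^2 / n2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  sp2[sp2 < 0] <- 0 # numerical guard
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- s1 / n1 - s2 / n2
  tt <- d / se
  tt[se == 0] <- 0
  tt
}

# Largest connected-component size, in edges, of the graph formed by the
# given (i, j) pairs. Union-find; cheap for the small suprathreshold sets a
# permutation typically produces.
max_component_edges <- function(pairs) {
  k <- nrow(pairs)
  if (k == 0L) return(0L)
  nodes <- unique(as.vector(pairs))
  id <- seq_along(nodes)
  names(id) <- nodes
  parent <- id
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- id[as.character(pairs[, 1])]
  b <- id[as.character(pairs[, 2])]
  for (e in seq_len(k)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(a, find, integer(1))
  max(tabulate(roots))
}

#' Network-based statistic (NBS)
#'
#' Mass-univariate comparison of every connection with cluster-level
#' family-wise error control: (1) a pooled-variance two-sample t-statistic
#' (lesion minus sham) is computed for each of the `R(R-1)/2` edges of the
#' *unthresholded* correlation matrices; (2) edges beyond the primary
#' threshold in the requested tail form a suprathreshold graph; (3) its
#' connected components are the candidate effects, sized by their edge count
#' (extent); (4) the null distribution of the maximal extent is built by
#' randomly relabeling subjects `n_perm` times; (5) each observed
#' component's FWER-corrected p-value is the fraction of permutations whose
#' maximal extent reaches its own, with the add-one correction
#' `(b + 1) / (n_perm + 1)`.
#'
#' Both one-sided contrasts are evaluated by default (`"less"`: connectivity
#' reduced in lesion; `"greater"`: increased), sharing one set of
#' permutations.
#'
#' @param matrices List of symmetric R x R correlation matrices, one per
#'   subject, in `design` order.
#' @param design A [group_design()].
#' @param primary_t Primary t-threshold (> 0) defining suprathreshold edges.
#' @param n_perm Number of random relabelings (>= 100).
#' @param tail Character vector among `"less"`, `"greater"`.
#' @param seed Optional seed; permutations are reproducible given it.
#' @param transform `"none"` (default) tests raw correlations; `"fisher"`
#'   applies the variance-stabilizing `atanh` first.
#' @return An object of class `nbs_result`: list with `primary_t`, `n_perm`,
#'   `n_nodes`, `tails` — for each tail a list with `components` (each a
#'   two-column matrix of edge node pairs with the edge t-statistics as
#'   attribute), `extents`, `p_fwer`, and the permutation `null_max`
#'   distribution.
#' @export
nbs <- function(matrices, design, primary_t = 3.1, n_perm = 5000L,
                tail = c("less", "greater"), seed = NULL,
                transform = c("none", "fisher")) {
  stopifnot(inherits(design, "group_design"))
  transform <- match.arg(transform)
  tail <- match.arg(tail, c("less", "greater"), several.ok = TRUE)
  if (!is.numeric(primary_t) || primary_t <= 0) {
    stopf("`primary_t` must be positive")
  }
  if (!is_count(n_perm, 100L)) stopf("`n_perm` must be a count >= 100")
  if (length(matrices) != length(design$labels)) {
    stopf("%d matrices but %d subjects in the design",
          length(matrices), length(design$labels))
  }
  if (design$n_lesion < 2L || design$n_sham < 2L) {
    stopf("each group needs >= 2 subjects")
  }
  ev <- edge_value_matrix(matrices)
  x <- ev$x
  if (transform == "fisher") {
    x <- atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
  }
  x2 <- x^2
  n <- nrow(x)
  n1 <- design$n_lesion
  n2 <- design$n_sham
  if (lchoose(n, n1) < log(n_perm)) {
    warning(sprintf(
      "only %.0f distinct relabelings exist, fewer than n_perm = %d",
      choose(n, n1), n_perm), call. = FALSE)
  }

  obs_assign <- matrix(design$labels == "lesion", 1L, n)
  t_obs <- edgewise_t_matrix(x, x2, obs_assign, n1, n2)[1L, ]

  # Permutation null of the maximal component extent, shared across tails.
  null_max <- with_opt_seed(seed, {
    out <- list(less = integer(n_perm), greater = integer(n_perm))
    chunk <- 250L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      assign1 <- matrix(FALSE, nb, n)
      for (b in seq_len(nb)) assign1[b, sample.int(n, n1)] <- TRUE
      tp <- edgewise_t_matrix(x, x2, assign1, n1, n2)
      for (b in seq_len(nb)) {
        if ("less" %in% tail) {
          out$less[done + b] <-
            max_component_edges(ev$pairs[tp[b, ] <= -primary_t, , drop = FALSE])
        }
        if ("greater" %in% tail) {
          out$greater[done + b] <-
            max_component_edges(ev$pairs[tp[b, ] >= primary_t, , drop = FALSE])
        }
      }
      done <- done + nb
    }
    out
  })

  tails <- lapply(stats::setNames(tail, tail), function(tl) {
    supra <- if (tl == "less") t_obs <= -primary_t else t_obs >= primary_t
    comp <- observed_components(ev$pairs[supra, , drop = FALSE],
                                t_obs[supra], ev$n_nodes)
    p <- vapply(comp$extents, function(ext) {
      (1 + sum(null_max[[tl]] >= ext)) / (n_perm + 1)
    }, numeric(1))
    list(components = comp$components, extents = comp$extents,
         p_fwer = p, null_max = null_max[[tl]])
  })

  structure(list(primary_t = primary_t, n_perm = as.integer(n_perm),
                 n_nodes = ev$n_nodes, transform = transform,
                 design = design, tails = tails),
            class = "nbs_result")
}

# Split suprathreshold edges into connected components (igraph), largest
# first; keeps each edge's t-statistic alongside.
observed_components <- function(pairs, t_values, n_nodes) {
  if (nrow(pairs) == 0L) {
    return(list(components = list(), extents = integer()))
  }
  ig <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  memb <- igraph::components(ig)$membership
  comp_of_edge <- memb[pairs[, 1]]
  comps <- lapply(split(seq_len(nrow(pairs)), comp_of_edge), function(idx) {
    m <- pairs[idx, , drop = FALSE]
    attr(m, "t") <- t_values[idx]
    m
  })
  extents <- vapply(comps, nrow, integer(1))
  ord <- order(extents, decreasing = TRUE)
  list(components = unname(comps[ord]), extents = unname(extents[ord]))
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> primary t = %.3g, %d permutations, %d nodes\n",
              x$primary_t, x$n_perm, x$n_nodes))
  for (tl in names(x$tails)) {
    res <- x$tails[[tl]]
    cat(sprintf("  tail '%s': %d component(s)\n", tl, length(res$extents)))
    if (length(res$extents)) {
      for (i in seq_along(res$extents)) {
        cat(sprintf("    component %d: %d edge(s), p_FWER = %.4f\n",
                    i, res$extents[i], res$p_fwer[i]))
      }
    }
  }
  invisible(x)
}

#' Per-node count of abnormal connections
#'
#' For every node, the number of edges belonging to significant NBS
#' components (`p_fwer < alpha`, across the requested tails) incident to
#' it — the quantity typically rendered as node size on a glass-brain plot.
#' Counts sum to twice the number of significant edges.
#'
#' @param res An [nbs()] result.
#' @param alpha Component-level significance threshold (default 0.05).
#' @param tail Tails to include (default: all present in `res`).
#' @return Integer vector of length `res$n_nodes`.
#' @export
summarize_node_involvement <- function(res, alpha = 0.05,
                                       tail = names(res$tails)) {
  stopifnot(inherits(res, "nbs_result"))
  counts <- integer(res$n_nodes)
  for (tl in tail) {
    t_res <- res$tails[[tl]]
    for (i in seq_along(t_res$components)) {
      if (t_res$p_fwer[i] < alpha) {
        inc <- tabulate(as.vector(t_res$components[[i]]), nbins = res$n_nodes)
        counts <- counts + inc
      }
    }
  }
  counts
}
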