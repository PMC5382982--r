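# Correlation matrices for n subjects drawn from one multivariate normal;
# group labels attached afterwards, so the group null holds by construction.
null_matrices <- function(n_subj, n_nodes, n_vol = 150) {
  lapply(seq_len(n_subj), function(i) {
    pearson_matrix(matrix(rnorm(n_vol * n_nodes), n_vol, n_nodes))
  })
}

toy_design <- function(n1 = 5, n2 = 5) {
  group_design(sprintf("s%02d", seq_len(n1 + n2)),
               c(rep("lesion", n1), rep("sham", n2)))
}

test_that("group_design validates labels and counts", {
  d <- toy_design(3, 4)
  expect_identical(d$n_lesion, 3L)
  expect_identical(d$n_sham, 4L)
  expect_error(group_design("a", "control"), "lesion")
  expect_error(group_design(c("a", "a"), c("lesion", "sham")), "duplicated")
  expect_error(group_design(c("a", "b"), c("lesion", "lesion")), "non-empty")
})

test_that("mixed ANOVA reproduces the hand-computed split-plot decomposition", {
  # 2 subjects per group, 2 sparsity levels; all sums of squares computable
  # by hand from the cell means.
  tab <- data.frame(
    subject = rep(c("l1", "l2", "s1", "s2"), each = 2),
    group = rep(c("lesion", "lesion", "sham", "sham"), each = 2),
    sparsity = rep(c(0.1, 0.2), 4),
    value = c(10, 12, 14, 18, 9, 11, 7, 11))
  res <- mixed_anova_global(tab)

  y <- tab$value
  grand <- mean(y)
  subj_means <- tapply(y, tab$subject, mean)
  grp_means <- tapply(y, tab$group, mean)
  sp_means <- tapply(y, tab$sparsity, mean)
  cell_means <- tapply(y, list(tab$group, tab$sparsity), mean)
  ss_group <- 4 * sum((grp_means - grand)^2)
  ss_subj_within <- 2 * sum((subj_means - grp_means[c(1, 1, 2, 2)])^2)
  ss_sp <- 4 * sum((sp_means - grand)^2)
  ss_int <- 2 * sum((cell_means - outer(grp_means - grand,
                                        sp_means - grand, "+") - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_resid <- ss_tot - ss_group - ss_subj_within - ss_sp - ss_int

  f_group <- (ss_group / 1) / (ss_subj_within / 2)
  f_sp <- (ss_sp / 1) / (ss_resid / 2)
  f_int <- (ss_int / 1) / (ss_resid / 2)

  a <- res$anova
  expect_equal(a$F[a$effect == "group"], f_group)
  expect_equal(a$F[a$effect == "sparsity"], f_sp)
  expect_equal(a$F[a$effect == "group:sparsity"], f_int)
  expect_equal(a$df2[a$effect == "group"], 2)
  expect_equal(a$df2[a$effect == "sparsity"], 2)
  # Bonferroni multiplies the per-threshold p by the number of thresholds
  expect_equal(res$posthoc$p_bonferroni,
               pmin(1, res$posthoc$p * 2))
})

test_that("with a single sparsity level the ANOVA degenerates to F = t^2", {
  set.seed(41)
  tab <- data.frame(subject = sprintf("s%d", 1:12),
                    group = rep(c("lesion", "sham"), each = 6),
                    sparsity = 0.2, value = rnorm(12))
  res <- mixed_anova_global(tab)
  tt <- t.test(value ~ group, data = tab, var.equal = TRUE)
  expect_equal(res$anova$F[1], unname(tt$statistic)^2)
  expect_equal(res$anova$p[1], tt$p.value)
})

test_that("a constant group offset is detected with high confidence", {
  set.seed(42)
  grid <- seq(0.1, 0.5, 0.1)
  tab <- expand.grid(subject = sprintf("s%d", 1:12), sparsity = grid)
  tab$group <- ifelse(as.integer(sub("s", "", tab$subject)) <= 6,
                      "lesion", "sham")
  tab$value <- rnorm(nrow(tab), sd = 0.1) +
    ifelse(tab$group == "lesion", 2, 0)
  res <- mixed_anova_global(tab)
  expect_lt(res$anova$p[res$anova$effect == "group"], 0.01)
})

test_that("nodal t-tests flag planted nodes with the right direction", {
  set.seed(43)
  d <- toy_design(8, 8)
  auc <- matrix(rnorm(16 * 30), 16, 30)
  auc[d$labels == "lesion", 1:5] <- auc[d$labels == "lesion", 1:5] - 3
  res <- nodal_auc_ttests(auc, d)
  expect_true(all(res$sig_uncorrected[1:5]))
  expect_true(all(res$direction[1:5] == "decrease"))
  expect_true(all(res$q_value >= res$p))

  same <- matrix(rnorm(16 * 4), 16, 4)
  same[d$labels == "sham", ] <- same[d$labels == "lesion", ] # identical groups
  res0 <- nodal_auc_ttests(same, d)
  expect_true(all(res0$t == 0))
  expect_false(any(res0$sig_uncorrected))

  const <- matrix(1, 16, 2)
  const[d$labels == "sham", 2] <- 2 # constant within groups, unequal means
  expect_error(nodal_auc_ttests(const, d), "zero variance")
})

test_that("BH q-values reproduce the step-up rule by hand", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))
  # monotone non-decreasing in sorted-p order, never below p
  set.seed(44)
  ps <- runif(50)
  qs <- p.adjust(ps, "BH")
  expect_true(all(qs >= ps))
  expect_true(all(diff(qs[order(ps)]) >= -1e-15))
})

test_that("NBS finds nothing above an unattainable threshold", {
  set.seed(45)
  mats <- null_matrices(10, 15)
  res <- nbs(mats, toy_design(5, 5), primary_t = 50, n_perm = 100, seed = 1)
  expect_length(res$tails$less$components, 0)
  expect_length(res$tails$greater$components, 0)
  expect_identical(summarize_node_involvement(res), integer(15))
})

test_that("NBS is reproducible and invariant to full label swap", {
  set.seed(46)
  mats <- null_matrices(12, 20)
  d <- toy_design(6, 6)
  a <- nbs(mats, d, primary_t = 2, n_perm = 200, seed = 7)
  b <- nbs(mats, d, primary_t = 2, n_perm = 200, seed = 7)
  expect_identical(a$tails$less$p_fwer, b$tails$less$p_fwer)
  expect_identical(a$tails$greater$extents, b$tails$greater$extents)

  # swapping every label exchanges the roles of the two tails
  d_swap <- group_design(d$subject_ids,
                         ifelse(d$labels == "lesion", "sham", "lesion"))
  s <- nbs(mats, d_swap, primary_t = 2, n_perm = 200, seed = 7)
  expect_identical(a$tails$less$extents, s$tails$greater$extents)
  expect_identical(a$tails$greater$extents, s$tails$less$extents)
})

test_that("NBS recovers a planted fully-connected effect block", {
  set.seed(47)
  n_nodes <- 30
  block <- 1:6
  mats <- lapply(1:20, function(i) {
    x <- matrix(rnorm(200 * n_nodes), 200, n_nodes)
    if (i <= 10) { # lesion subjects: correlated block signal removed
      x[, block] <- x[, block] + 0.8 * rnorm(200)
    } else {       # sham subjects: strong shared block signal
      x[, block] <- x[, block] + 2.0 * rnorm(200)
    }
    pearson_matrix(x)
  })
  res <- nbs(mats, toy_design(10, 10), primary_t = 3, n_perm = 500, seed = 8)
  expect_gte(length(res$tails$less$components), 1)
  comp <- res$tails$less$components[[1]]
  expect_lt(res$tails$less$p_fwer[1], 0.05)
  planted <- t(combn(block, 2))
  in_comp <- paste(comp[, 1], comp[, 2]) # component edges as keys
  hits <- sum(paste(planted[, 1], planted[, 2]) %in% in_comp)
  expect_gte(hits / nrow(planted), 0.8)
})

test_that("node involvement counts match a brute-force incidence count", {
  set.seed(48)
  mats <- null_matrices(12, 15)
  res <- nbs(mats, toy_design(6, 6), primary_t = 1.5, n_perm = 100, seed = 3)
  counts <- summarize_node_involvement(res, alpha = 1.01) # include everything
  all_edges <- do.call(rbind, c(res$tails$less$components,
                                res$tails$greater$components))
  expect_identical(counts, bf_node_incidence(all_edges, 15))
  expect_identical(sum(counts), 2L * nrow(all_edges))

  # a single significant triangle gives each node incidence 2
  expect_identical(bf_node_incidence(rbind(c(1, 2), c(2, 3), c(1, 3)), 5),
                   c(2L, 2L, 2L, 0L, 0L))
})

test_that("degenerate permutation spaces trigger a warning", {
  set.seed(49)
  mats <- null_matrices(5, 8)
  d <- group_design(sprintf("s%d", 1:5),
                    c("lesion", "lesion", "sham", "sham", "sham"))
  expect_warning(nbs(mats, d, primary_t = 2, n_perm = 100, seed = 1),
                 "distinct relabelings")
  expect_error(nbs(mats, d, primary_t = -1, n_perm = 100), "positive")
})
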