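#' Pipeline run configuration
#'
#' Assembles every parameter of the study replica — cohort and planted
#' effect, preprocessing settings, sparsity grid, random-reference count,
#' statistics settings and the master seed — into one validated object.
#' Defaults reproduce the reference analysis at full scale: a 0.05-0.5
#' sparsity grid in steps of 0.05, 100 random references, 10000 NBS
#' permutations at a primary threshold of t = 3.1, FDR q < 0.05.
#'
#' @param cohort A [cohort_spec()].
#' @param effect An [effect_spec()].
#' @param n_drop,f_low,f_high,filter_order,mask_target Preprocessing
#'   parameters (see [preprocess_subject()]).
#' @param grid Sparsity thresholds (see [sparsity_grid()]).
#' @param n_rand Random references per threshold for small-world
#'   normalization.
#' @param alpha,fdr_q Uncorrected and FDR significance levels.
#' @param primary_t,n_perm,tails NBS parameters (see [nbs()]).
#' @param edge_rank Edge ranking rule for thresholding.
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Directory the pipeline writes into.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), effect = null_effect(),
                       n_drop = 50L, f_low = 0.01, f_high = 0.1,
                       filter_order = 2L, mask_target = 300L,
                       grid = sparsity_grid(), n_rand = 100L,
                       alpha = 0.05, fdr_q = 0.05, primary_t = 3.1,
                       n_perm = 10000L, tails = c("less", "greater"),
                       edge_rank = "signed", seed = 1L,
                       output_dir = tempfile("rsfcnet_run_")) {
  structure(list(cohort = cohort, effect = effect, n_drop = n_drop,
                 f_low = f_low, f_high = f_high, filter_order = filter_order,
                 mask_target = mask_target, grid = grid, n_rand = n_rand,
                 alpha = alpha, fdr_q = fdr_q, primary_t = primary_t,
                 n_perm = n_perm, tails = tails, edge_rank = edge_rank,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every invariant of every sub-specification and returns the list of
#' violations (empty when the configuration is valid); messages name the
#' offending field.
#'
#' @param cfg A [run_config()].
#' @return Character vector of violation messages; `character(0)` if ok.
#' @export
validate_config <- function(cfg) {
  msg <- character()
  if (!inherits(cfg, "run_config")) return("cfg: not a run_config object")
  if (!inherits(cfg$cohort, "cohort_spec")) {
    msg <- c(msg, "cohort: not a cohort_spec")
  } else {
    msg <- c(msg, paste0("cohort: ", validate_cohort_spec(cfg$cohort)))
  }
  if (!inherits(cfg$effect, "effect_spec")) msg <- c(msg, "effect: not an effect_spec")
  if (!is_count(cfg$n_drop)) msg <- c(msg, "n_drop: must be a non-negative count")
  nyq <- if (inherits(cfg$cohort, "cohort_spec")) 1 / (2 * cfg$cohort$tr_seconds) else Inf
  if (!(cfg$f_low > 0 && cfg$f_low < cfg$f_high && cfg$f_high < nyq)) {
    msg <- c(msg, "band: need 0 < f_low < f_high < Nyquist")
  }
  if (!is_count(cfg$mask_target, 2L)) msg <- c(msg, "mask_target: must be a count >= 2")
  if (length(cfg$grid) < 2L || any(cfg$grid <= 0) || any(cfg$grid > 1) ||
      any(diff(cfg$grid) <= 0)) {
    msg <- c(msg, "grid: sparsity grid must be strictly increasing within (0, 1] with >= 2 points")
  }
  if (!is_count(cfg$n_rand)) msg <- c(msg, "n_rand: must be a non-negative count")
  for (f in c("alpha", "fdr_q")) {
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] > 0 && cfg[[f]] < 1)) {
      msg <- c(msg, sprintf("%s: must lie in (0, 1)", f))
    }
  }
  if (!(is.numeric(cfg$primary_t) && cfg$primary_t > 0)) {
    msg <- c(msg, "primary_t: must be positive")
  }
  if (!is_count(cfg$n_perm, 100L)) msg <- c(msg, "n_perm: must be a count >= 100")
  if (!all(cfg$tails %in% c("less", "greater")) || !length(cfg$tails)) {
    msg <- c(msg, "tails: must be a subset of {less, greater}")
  }
  if (inherits(cfg$cohort, "cohort_spec")) {
    n_after <- cfg$cohort$n_volumes - cfg$n_drop
    worst <- n_after - ceiling(cfg$cohort$spike_fraction * cfg$cohort$n_volumes)
    if (is_count(cfg$n_drop) && worst < cfg$mask_target) {
      msg <- c(msg, "mask_target: more volumes requested than can survive trimming and spike masking")
    }
  }
  msg[nzchar(msg) & !endsWith(msg, ": ")]
}

#' Run the full study replica
#'
#' Executes every stage in order — simulate, preprocess, connectome,
#' metrics, group statistics, NBS — writing all intermediate artifacts and a
#' JSON manifest (parameters, derived stage seeds, per-file MD5 checksums)
#' into `cfg$output_dir`. Re-running with the same configuration reproduces
#' identical outputs. Stage failures are re-signalled with the stage name.
#'
#' Output files: the cohort CSVs and manifest (`cohort/`), preprocessed
#' series (`preprocessed/`), correlation matrices (`connectome/`), tidy
#' metric tables `global_metrics.csv`, `nodal_metrics.csv`, `nodal_auc.csv`,
#' statistics tables `anova_global.csv`, `nodal_tests.csv`,
#' `nbs_edges.csv`, `node_involvement.csv`, and `run_manifest.json`.
#'
#' @param cfg A validated [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the key in-memory results (`profiles`,
#'   `anova`, `nodal_tests`, `nbs`) and `output_dir`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  violations <- validate_config(cfg)
  if (length(violations)) {
    stopf("invalid configuration:\n- %s", paste(violations, collapse = "\n- "))
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  seeds <- withr::with_seed(cfg$seed,
                            sample.int(.Machine$integer.max - 1L, 3L))
  names(seeds) <- c("cohort", "metrics", "nbs")

  say("stage simulate: %d + %d subjects, %d nodes, %d volumes",
      cfg$cohort$n_lesion, cfg$cohort$n_sham, cfg$cohort$n_nodes,
      cfg$cohort$n_volumes)
  cohort <- stage("simulate", {
    spec <- cfg$cohort
    spec$seed <- seeds[["cohort"]]
    coh <- generate_cohort(do.call(cohort_spec, unclass(spec)), cfg$effect)
    write_cohort(coh, file.path(cfg$output_dir, "cohort"))
    coh
  })

  say("stage preprocess: drop %d, band [%g, %g] Hz, mask to %d volumes",
      cfg$n_drop, cfg$f_low, cfg$f_high, cfg$mask_target)
  cleaned <- stage("preprocess", {
    dir.create(file.path(cfg$output_dir, "preprocessed"), showWarnings = FALSE)
    lapply(cohort$subjects, function(s) {
      out <- preprocess_subject(s$ts, s$nuisance, cfg$n_drop, cfg$f_low,
                                cfg$f_high, cfg$filter_order, cfg$mask_target)
      write.csv(as.data.frame(out$data),
                file.path(cfg$output_dir, "preprocessed",
                          paste0(out$subject_id, "_clean.csv")),
                row.names = FALSE)
      out
    })
  })

  say("stage connectome: %d x %d Pearson matrices",
      cfg$cohort$n_nodes, cfg$cohort$n_nodes)
  matrices <- stage("connectome", {
    dir.create(file.path(cfg$output_dir, "connectome"), showWarnings = FALSE)
    lapply(cleaned, function(ts) {
      r <- pearson_matrix(ts)
      write.csv(as.data.frame(r),
                file.path(cfg$output_dir, "connectome",
                          paste0(ts$subject_id, "_corr.csv")))
      r
    })
  })

  say("stage metrics: %d thresholds, %d random references",
      length(cfg$grid), cfg$n_rand)
  profiles <- stage("metrics", withr::with_seed(seeds[["metrics"]], {
    lapply(matrices, function(r) {
      subject_profile(r, cfg$grid, n_rand = cfg$n_rand,
                      edge_rank = cfg$edge_rank)
    })
  }))

  labels <- vapply(cohort$subjects, function(s) s$ts$group, "")
  design <- group_design(names(cohort$subjects), labels)

  results <- stage("stats", {
    bind <- function(field) {
      do.call(rbind, lapply(profiles, `[[`, field))
    }
    global <- bind("global")
    nodal <- bind("nodal")
    auc <- bind("auc")
    global$group <- labels[global$subject_id]
    write.csv(global, file.path(cfg$output_dir, "global_metrics.csv"),
              row.names = FALSE)
    write.csv(nodal, file.path(cfg$output_dir, "nodal_metrics.csv"),
              row.names = FALSE)
    write.csv(auc, file.path(cfg$output_dir, "nodal_auc.csv"),
              row.names = FALSE)

    metrics <- c("mean_clustering", "char_path_length", "global_efficiency",
                 "modularity", "n_modules",
                 if (cfg$n_rand > 0) c("c_norm", "l_norm", "small_world"))
    anova_tabs <- do.call(rbind, lapply(metrics, function(m) {
      tab <- mixed_anova_global(data.frame(
        subject = global$subject_id, group = global$group,
        sparsity = global$sparsity, value = global[[m]]))$anova
      cbind(metric = m, tab)
    }))
    write.csv(anova_tabs, file.path(cfg$output_dir, "anova_global.csv"),
              row.names = FALSE)

    nodal_tabs <- do.call(rbind, lapply(
      c("degree", "clustering", "efficiency"), function(measure) {
        sub <- auc[auc$measure == measure, ]
        mat <- matrix(NA_real_, length(design$subject_ids),
                      cfg$cohort$n_nodes)
        for (i in seq_along(design$subject_ids)) {
          rows <- sub[sub$subject_id == design$subject_ids[i], ]
          mat[i, rows$node] <- rows$auc
        }
        cbind(measure = measure,
              nodal_auc_ttests(mat, design, q = cfg$fdr_q, alpha = cfg$alpha))
      }))
    write.csv(nodal_tabs, file.path(cfg$output_dir, "nodal_tests.csv"),
              row.names = FALSE)
    list(anova = anova_tabs, nodal_tests = nodal_tabs)
  })

  say("stage nbs: primary t = %g, %d permutations", cfg$primary_t, cfg$n_perm)
  nbs_res <- stage("nbs", {
    res <- nbs(matrices, design, primary_t = cfg$primary_t,
               n_perm = cfg$n_perm, tail = cfg$tails,
               seed = seeds[["nbs"]])
    edges <- do.call(rbind, lapply(names(res$tails), function(tl) {
      t_res <- res$tails[[tl]]
      if (!length(t_res$components)) return(NULL)
      do.call(rbind, lapply(seq_along(t_res$components), function(i) {
        comp <- t_res$components[[i]]
        data.frame(tail = tl, component = i,
                   node_i = comp[, 1], node_j = comp[, 2],
                   t = attr(comp, "t"), p_fwer = t_res$p_fwer[i])
      }))
    }))
    if (is.null(edges)) {
      edges <- data.frame(tail = character(), component = integer(),
                          node_i = integer(), node_j = integer(),
                          t = numeric(), p_fwer = numeric())
    }
    write.csv(edges, file.path(cfg$output_dir, "nbs_edges.csv"),
              row.names = FALSE)
    involvement <- summarize_node_involvement(res, alpha = cfg$alpha)
    write.csv(data.frame(node = seq_along(involvement),
                         n_abnormal_connections = involvement),
              file.path(cfg$output_dir, "node_involvement.csv"),
              row.names = FALSE)
    res
  })

  manifest <- stage("manifest", {
    files <- list.files(cfg$output_dir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, file.path(cfg$output_dir, "run_manifest.json"))
    sums <- tools::md5sum(files)
    cfg_record <- unclass(cfg)
    cfg_record$cohort <- unclass(cfg_record$cohort)
    cfg_record$effect <- unclass(cfg_record$effect)
    man <- list(config = cfg_record,
                stage_seeds = as.list(seeds),
                checksums = as.list(stats::setNames(
                  unname(sums), substring(files, nchar(cfg$output_dir) + 2L))))
    path <- file.path(cfg$output_dir, "run_manifest.json")
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    man
  })

  invisible(list(profiles = profiles, anova = results$anova,
                 nodal_tests = results$nodal_tests, nbs = nbs_res,
                 design = design, manifest = manifest,
                 output_dir = cfg$output_dir))
}
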