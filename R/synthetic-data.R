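#' Cohort specification for synthetic rsfMRI time series
#'
#' Describes a two-group cohort of BOLD-like ROI time series with a modular
#' (community-structured) covariance. Defaults mirror a typical small-animal
#' acquisition: 900 one-second volumes over 150 ROIs (75 per hemisphere) in
#' 13 lesion and 11 sham subjects. Modules are bilateral: module `m` contains
#' a contiguous block of left-hemisphere ROIs and its mirrored
#' right-hemisphere block, so homotopic regions share a community.
#'
#' @param n_lesion,n_sham Subjects per group.
#' @param n_nodes Number of ROIs; must equal `2 * n_hemisphere`.
#' @param n_hemisphere ROIs per hemisphere; must be divisible by `n_modules`.
#' @param n_volumes Volumes (time points) per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param n_modules Number of bilateral covariance communities.
#' @param within_corr,between_corr Target Pearson correlation inside and
#'   between modules; `0 <= between_corr < within_corr < 1`.
#' @param drift_amplitude Amplitude of the per-ROI low-frequency (< 0.01 Hz)
#'   sinusoidal drift, in signal SD units.
#' @param spike_fraction Fraction of volumes corrupted by large-amplitude
#'   motion spikes (placed after volume 50); in `[0, 1)`.
#' @param seed Integer seed making the cohort reproducible.
#'
#' @return A list of class `cohort_spec`.
#' @seealso [generate_cohort()], [effect_spec()]
#' @export
cohort_spec <- function(n_lesion = 13, n_sham = 11, n_nodes = 150,
                        n_hemisphere = n_nodes / 2, n_volumes = 900,
                        tr_seconds = 1, n_modules = 5,
                        within_corr = 0.4, between_corr = 0.05,
                        drift_amplitude = 0.5, spike_fraction = 0.02,
                        seed = 1L) {
  spec <- list(n_lesion = n_lesion, n_sham = n_sham, n_nodes = n_nodes,
               n_hemisphere = n_hemisphere, n_volumes = n_volumes,
               tr_seconds = tr_seconds, n_modules = n_modules,
               within_corr = within_corr, between_corr = between_corr,
               drift_amplitude = drift_amplitude,
               spike_fraction = spike_fraction, seed = as.integer(seed))
  msg <- validate_cohort_spec(spec)
  if (length(msg)) stopf("invalid cohort_spec: %s", paste(msg, collapse = "; "))
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  msg <- character()
  if (!is_count(s$n_lesion, 1L)) msg <- c(msg, "n_lesion must be a positive count")
  if (!is_count(s$n_sham, 1L)) msg <- c(msg, "n_sham must be a positive count")
  if (!is_count(s$n_nodes, 2L) || s$n_nodes != 2 * s$n_hemisphere) {
    msg <- c(msg, "n_nodes must equal 2 * n_hemisphere")
  }
  if (!is_count(s$n_modules, 1L) || s$n_hemisphere %% s$n_modules != 0) {
    msg <- c(msg, "n_modules must divide n_hemisphere")
  }
  if (!is_count(s$n_volumes, 60L)) msg <- c(msg, "n_volumes must be a count >= 60")
  if (!is.numeric(s$tr_seconds) || s$tr_seconds <= 0) {
    msg <- c(msg, "tr_seconds must be positive")
  }
  if (!(s$between_corr >= 0 && s$between_corr < s$within_corr &&
        s$within_corr < 1)) {
    msg <- c(msg, "need 0 <= between_corr < within_corr < 1")
  }
  if (!is.numeric(s$drift_amplitude) || s$drift_amplitude < 0) {
    msg <- c(msg, "drift_amplitude must be >= 0")
  }
  if (!is.numeric(s$spike_fraction) || s$spike_fraction < 0 ||
      s$spike_fraction >= 1) {
    msg <- c(msg, "spike_fraction must lie in [0, 1)")
  }
  msg
}

#' Planted group effect for synthetic cohorts
#'
#' Defines how the lesion group's generating covariance deviates from the
#' sham group's: correlations within `reduced_block` are multiplied by
#' `reduction_factor` and every correlation between a block node and the
#' rest of the brain by its square root — the pattern obtained by scaling
#' the block nodes' community-factor loadings, so the whole connectivity of
#' the block is lost coherently (emulating an ipsilesional cortical deficit)
#' while the target remains a valid correlation matrix. `increased_block`
#' is treated the same way with `increase_factor` (a gain, emulating
#' bilateral thalamic hyperconnectivity). Diagonals are untouched, so
#' marginal variances stay comparable across groups and the planted
#' difference is purely in connectivity.
#'
#' @param reduced_block,increased_block Disjoint integer vectors of node
#'   indices. For the planted correlation change to be substantial, a block
#'   should lie within one covariance module of the cohort.
#' @param reduction_factor Multiplier in `(0, 1]` applied to off-diagonal
#'   covariance within `reduced_block` in the lesion group.
#' @param increase_factor Multiplier `>= 1` applied within `increased_block`.
#' @param null_flag If `TRUE`, both factors are forced to 1 and the two
#'   groups share a single generating distribution.
#'
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(reduced_block = integer(), increased_block = integer(),
                        reduction_factor = 0.5, increase_factor = 1.3,
                        null_flag = FALSE) {
  reduced_block <- as.integer(reduced_block)
  increased_block <- as.integer(increased_block)
  if (isTRUE(null_flag)) {
    reduction_factor <- 1
    increase_factor <- 1
  }
  if (length(intersect(reduced_block, increased_block))) {
    stopf("reduced_block and increased_block must be disjoint")
  }
  if (!is.numeric(reduction_factor) || reduction_factor <= 0 ||
      reduction_factor > 1) {
    stopf("reduction_factor must lie in (0, 1]")
  }
  if (!is.numeric(increase_factor) || increase_factor < 1) {
    stopf("increase_factor must be >= 1")
  }
  structure(list(reduced_block = reduced_block,
                 increased_block = increased_block,
                 reduction_factor = reduction_factor,
                 increase_factor = increase_factor,
                 null_flag = isTRUE(null_flag)),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
null_effect <- function() effect_spec(null_flag = TRUE)

# Bilateral module assignment: left ROIs 1..H, right ROIs H+1..2H; node i and
# its homotopic partner i+H belong to the same module.
module_assignment <- function(n_hemisphere, n_modules) {
  per <- n_hemisphere / n_modules
  left <- rep(seq_len(n_modules), each = per)
  c(left, left)
}

# Block correlation matrix: within_corr inside a module, between_corr outside.
base_correlation <- function(spec) {
  mod <- module_assignment(spec$n_hemisphere, spec$n_modules)
  same <- outer(mod, mod, "==")
  sig <- ifelse(same, spec$within_corr, spec$between_corr)
  diag(sig) <- 1
  sig
}

# Loading-style effect injection: within-block off-diagonals are multiplied
# by the factor and every block-to-rest entry by its square root — the
# pattern produced by scaling the block nodes' community-factor loadings by
# sqrt(factor). Unlike scaling the within-block entries alone (which is
# incompatible with positive definiteness next to strong block-to-module
# correlations and would force heavy global shrinkage), this keeps the
# target a valid correlation matrix while changing only connectivity that
# involves the block.
apply_effect <- function(sigma, effect) {
  if (effect$null_flag) return(sigma)
  scale_block <- function(sigma, block, factor) {
    if (length(block) < 1L || factor == 1) return(sigma)
    other <- setdiff(seq_len(nrow(sigma)), block)
    off <- diag(length(block)) == 0
    sigma[block, block][off] <- sigma[block, block][off] * factor
    sigma[block, other] <- sigma[block, other] * sqrt(factor)
    sigma[other, block] <- sigma[other, block] * sqrt(factor)
    sigma
  }
  sigma <- scale_block(sigma, effect$reduced_block, effect$reduction_factor)
  scale_block(sigma, effect$increased_block, effect$increase_factor)
}

# Smallest identity-shrinkage (convex combination weight, in `step`
# increments) under which the Cholesky factorization succeeds.
shrink_needed <- function(sigma, step = 0.02, max_shrink = 0.5) {
  eps <- 0
  repeat {
    s <- (1 - eps) * sigma + eps * diag(nrow(sigma))
    ok <- !inherits(tryCatch(chol(s), error = identity), "error")
    if (ok) return(eps)
    eps <- eps + step
    if (eps > max_shrink) {
      stopf("correlation target infeasible: not positive definite even after %.0f%% shrinkage",
            100 * max_shrink)
    }
  }
}

apply_shrink <- function(sigma, eps) {
  s <- (1 - eps) * sigma + eps * diag(nrow(sigma))
  list(sigma = s, chol = chol(s), shrink = eps)
}

#' Generate a synthetic two-group cohort
#'
#' Draws each subject's volumes-by-ROIs series from a multivariate normal
#' with the cohort's modular block correlation (lesion subjects from the
#' effect-modified covariance), then layers on the nuisance structure the
#' preprocessing stage is designed to remove: per-ROI sinusoidal drift below
#' 0.01 Hz, a low-pass "CSF" signal partially mixed into every ROI, six
#' smooth random-walk motion traces, and `spike_fraction` of volumes (always
#' after volume 50, so an initial-volume trim never absorbs them) corrupted
#' by large offsets and flagged invalid.
#'
#' @param cohort A [cohort_spec()].
#' @param effect An [effect_spec()]; defaults to no group difference.
#'
#' @return A list of class `cohort` with elements:
#'   * `subjects`: list of per-subject lists, each with `ts` (an [roi_ts()])
#'     and `nuisance` (a volumes x 7 matrix, columns `mot1..mot6`, `csf`);
#'   * `cohort`, `effect`: the input specifications;
#'   * `target_correlation`: the generating correlation matrix per group.
#'
#' Output is bitwise reproducible given `cohort$seed`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_lesion = 2, n_sham = 2, n_nodes = 20,
#'                                    n_volumes = 120, n_modules = 2))
#' length(coh$subjects)
#' @export
generate_cohort <- function(cohort, effect = null_effect()) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(effect, "effect_spec"))
  bad <- setdiff(c(effect$reduced_block, effect$increased_block),
                 seq_len(cohort$n_nodes))
  if (length(bad)) stopf("effect block indices out of range: %s",
                         paste(bad, collapse = ","))

  # One shrink factor, shared by both groups, keeps the group difference
  # exactly the planted block pattern: shrinking only the group whose target
  # fails the positive-definiteness check would scale all of its
  # correlations and plant a global difference instead.
  base <- base_correlation(cohort)
  lesioned <- if (effect$null_flag) base else apply_effect(base, effect)
  eps <- max(shrink_needed(base), shrink_needed(lesioned))
  if (eps > 0) {
    warning(sprintf(
      "effect-modified correlation target not positive definite; both groups shrunk %.0f%% toward identity",
      100 * eps), call. = FALSE)
  }
  sig_sham <- apply_shrink(base, eps)
  sig_lesion <- if (effect$null_flag) sig_sham else apply_shrink(lesioned, eps)

  n_spike <- ceiling(cohort$spike_fraction * cohort$n_volumes)
  if (n_spike > cohort$n_volumes - 50L) {
    stopf("spike_fraction too high: %d spikes do not fit after volume 50", n_spike)
  }

  groups <- c(rep("lesion", cohort$n_lesion), rep("sham", cohort$n_sham))
  ids <- c(sprintf("lesion_%02d", seq_len(cohort$n_lesion)),
           sprintf("sham_%02d", seq_len(cohort$n_sham)))

  subjects <- withr::with_seed(cohort$seed, lapply(seq_along(ids), function(k) {
    ch <- if (groups[k] == "lesion") sig_lesion$chol else sig_sham$chol
    simulate_subject(cohort, ch, ids[k], groups[k], n_spike)
  }))
  names(subjects) <- ids

  structure(list(subjects = subjects, cohort = cohort, effect = effect,
                 target_correlation = list(lesion = sig_lesion$sigma,
                                           sham = sig_sham$sigma)),
            class = "cohort")
}

simulate_subject <- function(spec, chol_upper, id, group, n_spike) {
  T <- spec$n_volumes
  R <- spec$n_nodes
  x <- matrix(rnorm(T * R), T, R) %*% chol_upper

  # slow sinusoidal drift, one frequency/phase per ROI, all below 0.01 Hz
  tt <- (seq_len(T) - 1) * spec$tr_seconds
  freq <- runif(R, 0.001, 0.008)
  phase <- runif(R, 0, 2 * pi)
  x <- x + spec$drift_amplitude *
    sin(sweep(outer(tt, 2 * pi * freq), 2, phase, "+"))

  # CSF-like low-pass noise mixed into every ROI with a random weight
  csf <- as.numeric(stats::filter(rnorm(T), rep(1 / 8, 8), circular = TRUE))
  x <- x + outer(csf, runif(R, 0.2, 0.6))

  # six smooth random-walk motion traces (3 translations, 3 rotations)
  mot <- vapply(seq_len(6), function(j) {
    as.numeric(stats::filter(cumsum(rnorm(T, 0, 0.02)), rep(1 / 9, 9),
                             circular = TRUE))
  }, numeric(T))

  valid <- rep(TRUE, T)
  if (n_spike > 0) {
    idx <- sample((51L):T, n_spike)
    amp <- matrix(sample(c(-1, 1), n_spike * R, replace = TRUE) *
                    runif(n_spike * R, 6, 10), n_spike, R)
    x[idx, ] <- x[idx, ] + amp
    valid[idx] <- FALSE
  }

  nuis <- cbind(mot, csf)
  colnames(nuis) <- c(paste0("mot", 1:6), "csf")
  list(ts = roi_ts(x, id, group, spec$tr_seconds, valid), nuisance = nuis)
}

#' Ring-lattice and Erdos-Renyi test graphs
#'
#' `make_lattice_graph()` builds the ring lattice in which every node is
#' joined to its `k` nearest neighbours (`k/2` on each side); a regular graph
#' with `n * k / 2` edges and high clustering, the classic small-world
#' reference. `make_random_graph()` samples `m` distinct edges uniformly
#' without replacement from all `n(n-1)/2` node pairs (the G(n, m) model).
#'
#' @param n Number of nodes.
#' @param k Even neighbour count, `k < n`.
#' @param m Number of edges, `0 <= m <= n(n-1)/2`.
#' @param seed Optional seed for reproducible sampling.
#' @return A [binary_graph()].
#' @export
make_lattice_graph <- function(n, k) {
  if (!is_count(n, 3L)) stopf("`n` must be a count >= 3")
  if (!is_count(k, 0L) || k %% 2 != 0) stopf("`k` must be an even count")
  if (k >= n) stopf("`k` must be smaller than `n` (got k=%d, n=%d)", k, n)
  adj <- matrix(0L, n, n)
  for (off in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1L + off) %% n) + 1L
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  binary_graph(adj, sparsity = (n * k / 2) / choose(n, 2))
}

#' @rdname make_lattice_graph
#' @export
make_random_graph <- function(n, m, seed = NULL) {
  if (!is_count(n, 2L)) stopf("`n` must be a count >= 2")
  npairs <- n * (n - 1) / 2
  if (!is_count(m, 0L) || m > npairs) {
    stopf("`m` must lie in [0, %d] for n = %d", npairs, n)
  }
  pairs <- upper_pairs(n)
  pick <- with_opt_seed(seed, sample.int(npairs, m))
  adj <- matrix(0L, n, n)
  adj[pairs[pick, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  binary_graph(adj, sparsity = m / npairs)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` lays a generated cohort out on disk: one time-series CSV
#' per subject (columns `ROI_001..ROI_<R>` plus a 0/1 `valid` flag column),
#' one nuisance CSV per subject (columns `mot1..mot6`, `csf`), and a JSON
#' manifest recording subject ids, group labels, file paths and the
#' generating seed. `read_cohort()` reconstructs the subject list from such
#' a directory.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a list with `subjects` (as in
#'   [generate_cohort()]) and the manifest.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    id <- s$ts$subject_id
    ts_file <- file.path(dir, paste0(id, "_ts.csv"))
    nu_file <- file.path(dir, paste0(id, "_nuisance.csv"))
    df <- as.data.frame(s$ts$data)
    df$valid <- as.integer(s$ts$valid)
    write.csv(df, ts_file, row.names = FALSE)
    write.csv(as.data.frame(s$nuisance), nu_file, row.names = FALSE)
    list(subject_id = id, group = s$ts$group,
         ts_file = basename(ts_file), nuisance_file = basename(nu_file))
  })
  manifest <- list(seed = cohort$cohort$seed,
                   tr_seconds = cohort$cohort$tr_seconds,
                   n_nodes = cohort$cohort$n_nodes,
                   n_volumes = cohort$cohort$n_volumes,
                   subjects = rows)
  path <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                                  simplifyVector = FALSE)
  subjects <- lapply(manifest$subjects, function(row) {
    df <- read.csv(file.path(dir, row$ts_file), check.names = FALSE)
    valid <- as.logical(df$valid)
    data <- as.matrix(df[, setdiff(names(df), "valid"), drop = FALSE])
    nuis <- as.matrix(read.csv(file.path(dir, row$nuisance_file)))
    list(ts = roi_ts(data, row$subject_id, row$group,
                     manifest$tr_seconds, valid),
         nuisance = nuis)
  })
  names(subjects) <- vapply(manifest$subjects, `[[`, "", "subject_id")
  list(subjects = subjects, manifest = manifest)
}
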