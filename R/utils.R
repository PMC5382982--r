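# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, column-major order.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x) && x >= min
}

roi_names <- function(n) sprintf("ROI_%03d", seq_len(n))

# Run `expr` under `seed` when given, leaving the caller's RNG untouched;
# with seed = NULL the current RNG stream is consumed as usual.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
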