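#' ROI time-series container
#'
#' Bundles one subject's volumes-by-ROIs BOLD-like signal matrix with its
#' sampling interval, group label and per-volume validity flags. All
#' preprocessing operations consume and return `roi_ts` objects.
#'
#' @param data Numeric matrix, T volumes (rows) by R ROIs (columns). All
#'   values must be finite; T >= 2 and R >= 2.
#' @param subject_id Character scalar identifying the subject.
#' @param group Group label, `"lesion"` or `"sham"`.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param valid Logical vector of length T; `FALSE` marks volumes carrying
#'   movement or scanning artifacts. Defaults to all valid.
#'
#' @return An object of class `roi_ts`: a list with elements `data`,
#'   `subject_id`, `group`, `tr_seconds` and `valid`.
#' @examples
#' ts <- roi_ts(matrix(rnorm(40), 10, 4), "s01", "sham")
#' dim(ts$data)
#' @export
roi_ts <- function(data, subject_id, group = c("lesion", "sham"),
                   tr_seconds = 1, valid = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stopf("`data` needs >= 2 volumes and >= 2 ROIs, got %d x %d",
          nrow(data), ncol(data))
  }
  if (!all(is.finite(data))) stopf("`data` contains non-finite values")
  group <- match.arg(group)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stopf("`tr_seconds` must be a positive scalar")
  }
  if (is.null(valid)) valid <- rep(TRUE, nrow(data))
  if (!is.logical(valid) || length(valid) != nrow(data) || anyNA(valid)) {
    stopf("`valid` must be a complete logical vector of length %d", nrow(data))
  }
  if (is.null(colnames(data))) colnames(data) <- roi_names(ncol(data))
  structure(
    list(data = data, subject_id = as.character(subject_id), group = group,
         tr_seconds = as.numeric(tr_seconds), valid = valid),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf(
    "<roi_ts> subject %s (%s): %d volumes x %d ROIs, TR %.3g s, %d invalid volume(s)\n",
    x$subject_id, x$group, nrow(x$data), ncol(x$data), x$tr_seconds,
    sum(!x$valid)))
  invisible(x)
}

# Rebuild an roi_ts after an operation changed its data/flags.
replace_ts_data <- function(ts, data, valid = ts$valid) {
  roi_ts(data, ts$subject_id, ts$group, ts$tr_seconds, valid)
}
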