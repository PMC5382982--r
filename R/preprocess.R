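#' Remove initial saturation volumes
#'
#' Drops the first `n_drop` volumes (default 50) of a series, with their
#' validity flags, to exclude magnetization saturation effects at the start
#' of an EPI acquisition.
#'
#' @param ts An [roi_ts()].
#' @param n_drop Number of leading volumes to remove; must be `< T`.
#' @return The trimmed [roi_ts()].
#' @export
drop_initial_volumes <- function(ts, n_drop = 50L) {
  stopifnot(inherits(ts, "roi_ts"))
  if (!is_count(n_drop)) stopf("`n_drop` must be a non-negative count")
  T <- nrow(ts$data)
  if (n_drop >= T) stopf("cannot drop %d of %d volumes", n_drop, T)
  if (n_drop == 0L) return(ts)
  keep <- (n_drop + 1L):T
  replace_ts_data(ts, ts$data[keep, , drop = FALSE], ts$valid[keep])
}

#' Regress nuisance signals out of ROI time courses
#'
#' Replaces every ROI column by its ordinary-least-squares residual against
#' an intercept plus the nuisance regressors (typically the six rigid-body
#' realignment parameters and the mean CSF signal). Residuals are exactly
#' orthogonal to each regressor column, so motion- and CSF-driven variance
#' cannot masquerade as functional connectivity downstream. An intercept is
#' always included: residualizing without one leaves mean offsets that
#' corrupt correlations.
#'
#' @param ts An [roi_ts()].
#' @param nuisance Numeric matrix, one row per volume, one column per
#'   regressor (e.g. `mot1..mot6`, `csf`).
#' @return The residualized [roi_ts()].
#' @export
regress_nuisance <- function(ts, nuisance) {
  stopifnot(inherits(ts, "roi_ts"))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts$data)) {
    stopf("nuisance has %d rows but the series has %d volumes",
          nrow(nuisance), nrow(ts$data))
  }
  if (!all(is.finite(nuisance))) stopf("nuisance regressors must be finite")
  design <- cbind(intercept = 1, nuisance)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stopf("nuisance design is rank deficient (rank %d < %d columns); remove duplicated or constant regressors",
          qrd$rank, ncol(design))
  }
  replace_ts_data(ts, qr.resid(qrd, ts$data))
}

#' Band-pass filter ROI time courses
#'
#' Zero-phase (forward-backward) Butterworth band-pass, applied per ROI
#' column after de-meaning (the mean is not restored; the DC component lies
#' outside the pass band by construction). The default 0.01-0.1 Hz band is
#' the standard resting-state window: it suppresses scanner drift below and
#' respiratory/cardiac nuisance above the haemodynamic frequencies of
#' interest.
#'
#' @param ts An [roi_ts()].
#' @param f_low,f_high Band edges in Hz; require
#'   `0 < f_low < f_high < 1/(2 * tr_seconds)` (the Nyquist frequency).
#' @param order One-pass Butterworth order; the forward-backward application
#'   doubles it, so the default 2 yields a 4th-order effective response.
#' @return The filtered [roi_ts()].
#' @export
bandpass_filter <- function(ts, f_low = 0.01, f_high = 0.1, order = 2L) {
  stopifnot(inherits(ts, "roi_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(f_low > 0 && f_low < f_high && f_high < nyquist)) {
    stopf("need 0 < f_low < f_high < Nyquist (%.4g Hz); got [%g, %g]",
          nyquist, f_low, f_high)
  }
  if (!is_count(order, 1L)) stopf("`order` must be a positive count")
  bf <- signal::butter(order, c(f_low, f_high) / nyquist, type = "pass")
  centered <- sweep(ts$data, 2, colMeans(ts$data))
  filtered <- apply(centered, 2, function(x) signal::filtfilt(bf, x))
  replace_ts_data(ts, filtered)
}

#' Temporal masking to a fixed number of artifact-free volumes
#'
#' Reduces a series to exactly `target` volumes using only volumes whose
#' validity flag is `TRUE`: if the first `target` volumes are all valid they
#' are taken as a continuous block; otherwise valid volumes are concatenated
#' in temporal order until `target` is reached, producing a non-continuous
#' series. This is appropriate under the stationarity assumption that the
#' functional network does not change over the acquisition.
#'
#' @param ts An [roi_ts()].
#' @param target Number of volumes to keep (default 300); the subject is
#'   unusable (an error) when fewer valid volumes exist.
#' @return An [roi_ts()] with exactly `target` rows, all flagged valid.
#' @export
temporal_mask <- function(ts, target = 300L) {
  stopifnot(inherits(ts, "roi_ts"))
  if (!is_count(target, 2L)) stopf("`target` must be a count >= 2")
  n_valid <- sum(ts$valid)
  if (n_valid < target) {
    stopf("subject %s unusable: only %d valid volumes, %d required",
          ts$subject_id, n_valid, target)
  }
  keep <- if (all(ts$valid[seq_len(target)])) {
    seq_len(target)
  } else {
    which(ts$valid)[seq_len(target)]
  }
  replace_ts_data(ts, ts$data[keep, , drop = FALSE], rep(TRUE, target))
}

#' Average voxel time courses into ROI time courses
#'
#' Column `r` of the result is, for each volume, the arithmetic mean of all
#' voxels carrying label `r`. Every label `1..max(labels)` must be present;
#' an empty ROI is an error.
#'
#' @param voxels Numeric matrix, volumes x voxels.
#' @param labels Integer vector, one ROI label per voxel, values in `1..R`.
#' @param subject_id,group,tr_seconds,valid Metadata for the resulting
#'   [roi_ts()]; see [roi_ts()].
#' @return An [roi_ts()] with `R = max(labels)` columns.
#' @export
extract_roi_means <- function(voxels, labels, subject_id = "subject",
                              group = "sham", tr_seconds = 1, valid = NULL) {
  voxels <- as.matrix(voxels)
  labels <- as.integer(labels)
  if (length(labels) != ncol(voxels)) {
    stopf("`labels` must have one entry per voxel column")
  }
  if (any(labels < 1L)) stopf("ROI labels must be positive integers")
  n_roi <- max(labels)
  missing <- setdiff(seq_len(n_roi), unique(labels))
  if (length(missing)) {
    stopf("empty ROI(s) with no voxels: %s", paste(missing, collapse = ","))
  }
  means <- vapply(seq_len(n_roi), function(r) {
    rowMeans(voxels[, labels == r, drop = FALSE])
  }, numeric(nrow(voxels)))
  colnames(means) <- roi_names(n_roi)
  roi_ts(means, subject_id, group, tr_seconds, valid)
}

#' Interpolate over artifact volumes
#'
#' Replaces the signal in volumes flagged invalid by linear interpolation
#' between the nearest valid volumes (constant extrapolation at the ends),
#' per ROI. Validity flags are kept, so temporal masking still discards
#' these volumes; interpolation only prevents large-amplitude artifacts from
#' leaking into neighbouring valid volumes through the band-pass filter's
#' impulse response, and from acting as high-leverage points in the nuisance
#' regression. A no-op when all volumes are valid.
#'
#' @param ts An [roi_ts()] with at least 2 valid volumes.
#' @return An [roi_ts()] with identical flags and interpolated invalid rows.
#' @export
interpolate_invalid_volumes <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  bad <- which(!ts$valid)
  if (!length(bad)) return(ts)
  good <- which(ts$valid)
  if (length(good) < 2L) stopf("need >= 2 valid volumes to interpolate")
  data <- ts$data
  for (j in seq_len(ncol(data))) {
    data[bad, j] <- stats::approx(good, data[good, j], xout = bad,
                                  rule = 2)$y
  }
  replace_ts_data(ts, data)
}

#' Flag high-motion volumes from realignment parameters
#'
#' Convenience helper for data arriving without explicit validity flags:
#' marks a volume invalid when any frame-to-frame change in the translation
#' parameters exceeds `trans_threshold` (mm) or in the rotation parameters
#' exceeds `rot_threshold` (degrees). Thresholds default to the conventional
#' 2.5 mm / 2.5 degree exclusion rule.
#'
#' @param motion Matrix with >= 6 columns: three translations then three
#'   rotations, one row per volume.
#' @param trans_threshold,rot_threshold Exclusion thresholds.
#' @return Logical vector, `TRUE` for volumes deemed artifact-free.
#' @export
flag_motion_volumes <- function(motion, trans_threshold = 2.5,
                                rot_threshold = 2.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6L) stopf("`motion` needs 6 columns (3 trans + 3 rot)")
  d <- abs(apply(motion[, 1:6, drop = FALSE], 2, function(x) c(0, diff(x))))
  bad <- apply(d[, 1:3, drop = FALSE], 1, max) > trans_threshold |
    apply(d[, 4:6, drop = FALSE], 1, max) > rot_threshold
  !bad
}

#' Full per-subject preprocessing chain
#'
#' Applies, in fixed order: initial-volume removal, interpolation over
#' flagged artifact volumes (see [interpolate_invalid_volumes()]), nuisance
#' regression (regressor rows trimmed to match), zero-phase band-pass
#' filtering of the continuous series, then temporal masking to `target`
#' artifact-free volumes. Filtering precedes masking so the filter always
#' sees a continuous time axis, and interpolation precedes regression and
#' filtering so spike artifacts can neither bias the nuisance fit nor ring
#' through the filter into valid volumes.
#'
#' @param ts An [roi_ts()].
#' @param nuisance Volumes x regressors matrix aligned with the *untrimmed*
#'   series.
#' @param n_drop,f_low,f_high,filter_order,target Stage parameters; see the
#'   individual stage functions.
#' @return An [roi_ts()] with exactly `target` rows.
#' @export
preprocess_subject <- function(ts, nuisance, n_drop = 50L, f_low = 0.01,
                               f_high = 0.1, filter_order = 2L,
                               target = 300L) {
  stopifnot(inherits(ts, "roi_ts"))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts$data)) {
    stopf("nuisance rows (%d) must match the untrimmed series (%d volumes)",
          nrow(nuisance), nrow(ts$data))
  }
  out <- drop_initial_volumes(ts, n_drop)
  out <- interpolate_invalid_volumes(out)
  nuis <- nuisance[(n_drop + 1L):nrow(nuisance), , drop = FALSE]
  out <- regress_nuisance(out, nuis)
  out <- bandpass_filter(out, f_low, f_high, filter_order)
  temporal_mask(out, target)
}
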