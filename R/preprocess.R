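#' Band-pass filter regional time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied column-wise.
#' Column means are removed before filtering so the retained band excludes
#' the DC component. The default band, 0.01-0.1 Hz, is the standard
#' resting-state frequency range.
#'
#' @param ts an [roi_ts()] object.
#' @param low_hz lower edge in Hz.
#' @param high_hz upper edge in Hz; must satisfy
#'   `0 <= low_hz < high_hz < 1/(2 TR)`.
#' @param order Butterworth order (of the prototype low/high-pass; the
#'   band-pass has twice this order, applied twice for zero phase).
#' @return an `roi_ts` with filtered data; shape and labels unchanged.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1, order = 2) {
  stopifnot(inherits(ts, "roi_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "band (%g, %g) Hz invalid: need 0 <= low < high < Nyquist = %g Hz",
      low_hz, high_hz, nyq))
  filt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  x <- scale(ts$data, center = TRUE, scale = FALSE)
  y <- apply(x, 2, function(col) signal::filtfilt(filt, col))
  ts$data <- matrix(y, nrow(ts$data), ncol(ts$data),
                    dimnames = dimnames(ts$data))
  ts
}

#' Power framewise displacement
#'
#' Per-volume head-motion summary: the sum of absolute backward differences
#' of the three translations (mm) plus the rotations (radians) converted to
#' arc length on a sphere of radius `sphere_radius_mm`. The first volume has
#' no predecessor and is assigned FD = 0 by convention.
#'
#' @param motion `T x 6` matrix (tx, ty, tz mm; rx, ry, rz radians) or an
#'   `roi_ts` carrying one.
#' @param sphere_radius_mm rotation-to-displacement radius; 50 mm is the
#'   standard choice (approximate distance from the centre of the head to
#'   the cortex).
#' @param rotation_units `"radians"` (default) or `"degrees"`.
#' @return numeric vector of length `T`.
#' @export
power_fd <- function(motion, sphere_radius_mm = 50,
                     rotation_units = c("radians", "degrees")) {
  if (inherits(motion, "roi_ts")) motion <- motion$motion
  motion <- as.matrix(motion)
  rotation_units <- match.arg(rotation_units)
  if (ncol(motion) != 6L)
    stop("motion must have 6 columns (tx, ty, tz, rx, ry, rz)")
  if (nrow(motion) < 2L) stop("need at least 2 volumes to compute FD")
  rot <- motion[, 4:6, drop = FALSE]
  if (rotation_units == "degrees") rot <- rot * pi / 180
  d_trans <- abs(diff(motion[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot))
  c(0, rowSums(d_trans) + sphere_radius_mm * rowSums(d_rot))
}

#' Motion scrubbing (censoring) by framewise displacement
#'
#' Flags every volume whose FD exceeds `threshold`, together with its
#' immediate predecessor and successor, and removes the flagged volumes
#' from the series so that connectivity is estimated on retained volumes
#' only.
#'
#' @param ts an [roi_ts()].
#' @param fd FD vector from [power_fd()]; length must match the series.
#' @param threshold FD threshold (default 1, the conventional lenient cut).
#' @param mode `"censor"` (default) deletes flagged volumes; `"spike"`
#'   keeps all volumes and instead returns one indicator regressor per
#'   flagged volume in the mask's `spike_regressors`, for use as nuisance
#'   columns.
#' @return list with elements `ts` (the scrubbed series) and `mask` (class
#'   `scrub_mask`: `fd`, logical `flags`, and for spike mode a `T x k`
#'   indicator matrix `spike_regressors`).
#' @export
scrub <- function(ts, fd, threshold = 1, mode = c("censor", "spike")) {
  stopifnot(inherits(ts, "roi_ts"))
  mode <- match.arg(mode)
  n <- nrow(ts$data)
  if (length(fd) != n) stop("fd length must match the number of volumes")
  bad <- which(fd > threshold)
  flags <- rep(FALSE, n)
  if (length(bad))
    flags[unique(pmax(1L, pmin(n, c(bad - 1L, bad, bad + 1L))))] <- TRUE
  if (all(flags)) stop("no usable volumes: every volume is flagged")
  if (mean(flags) > 0.5)
    warning(sprintf("%.0f%% of volumes flagged for scrubbing", 100 * mean(flags)))
  mask <- structure(list(fd = fd, flags = flags, threshold = threshold,
                         spike_regressors = NULL),
                    class = "scrub_mask")
  if (mode == "censor") {
    if (any(flags)) {
      ts$data <- ts$data[!flags, , drop = FALSE]
      if (!is.null(ts$motion)) ts$motion <- ts$motion[!flags, , drop = FALSE]
    }
  } else if (any(flags)) {
    idx <- which(flags)
    S <- matrix(0, n, length(idx))
    S[cbind(idx, seq_along(idx))] <- 1
    mask$spike_regressors <- S
  }
  list(ts = ts, mask = mask)
}

#' Write a scrub mask as a two-column TSV (fd, flagged)
#'
#' @param mask a `scrub_mask`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scrub_mask <- function(mask, path) {
  df <- data.frame(fd = formatC(mask$fd, digits = 12, format = "g"),
                   flagged = as.integer(mask$flags))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Friston 24-parameter motion expansion
#'
#' Expands the six rigid-body parameters into the 24-column nuisance set:
#' the parameters, their one-volume backward lag, their squares, and the
#' squared lags. Lag rows at t = 1 are zero-filled.
#'
#' @param motion `T x 6` motion matrix or an `roi_ts` carrying one.
#' @return `T x 24` numeric matrix.
#' @export
expand_motion_24 <- function(motion) {
  if (inherits(motion, "roi_ts")) motion <- motion$motion
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 volumes")
  lagged <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  cbind(motion, lagged, motion^2, lagged^2)
}

#' Nuisance (confound) regression
#'
#' Regresses each regional time series on an intercept plus the supplied
#' confound columns and returns the residuals, removing e.g. white-matter
#' and CSF signals and the 24-parameter motion expansion before
#' connectivity estimation. Redundant (rank-deficient) confound columns are
#' dropped with a warning.
#'
#' @param ts an [roi_ts()].
#' @param confounds `T x C` numeric matrix.
#' @return an `roi_ts` of residuals; shape and labels unchanged.
#' @export
nuisance_regress <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_ts"))
  confounds <- as.matrix(confounds)
  n <- nrow(ts$data)
  if (nrow(confounds) != n)
    stop("confounds must have one row per volume")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- ncol(X) - qrX$rank
    warning(sprintf("dropping %d redundant confound column(s)", dropped))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  if (qrX$rank >= n)
    stop("confound model saturates the data (rank >= number of volumes)")
  ts$data <- qr.resid(qrX, ts$data)
  dimnames(ts$data) <- list(NULL, ts$roi_labels)
  ts
}

#' Run the default cleaning chain on one series
#'
#' Order: scrubbing (when a motion table and FD rule are available), then
#' nuisance regression (24-parameter motion expansion plus any extra
#' confound columns), then band-pass filtering. Each stage preserves the
#' ROI count and labels. Stages are skipped gracefully when their inputs
#' are absent (no motion table: no scrubbing or motion regression).
#'
#' @param ts an [roi_ts()].
#' @param band length-2 numeric, band edges in Hz; `NULL` skips filtering.
#' @param fd_threshold FD scrubbing threshold; `NULL` skips scrubbing.
#' @param fd_radius_mm rotation sphere radius for FD.
#' @param rotation_units `"radians"` or `"degrees"`.
#' @param extra_confounds optional `T x C` matrix (e.g. WM/CSF signals),
#'   rows matching the unscrubbed series.
#' @param scrub_mode `"censor"` or `"spike"`.
#' @return an `roi_ts`, cleaned.
#' @export
preprocess_ts <- function(ts, band = c(0.01, 0.1), fd_threshold = 1,
                          fd_radius_mm = 50,
                          rotation_units = "radians",
                          extra_confounds = NULL,
                          scrub_mode = "censor") {
  stopifnot(inherits(ts, "roi_ts"))
  confounds <- NULL
  if (!is.null(ts$motion)) {
    if (!is.null(fd_threshold)) {
      fd <- power_fd(ts$motion, sphere_radius_mm = fd_radius_mm,
                     rotation_units = rotation_units)
      sc <- scrub(ts, fd, threshold = fd_threshold, mode = scrub_mode)
      ts <- sc$ts
      if (!is.null(sc$mask$spike_regressors))
        confounds <- cbind(confounds, sc$mask$spike_regressors)
      if (!is.null(extra_confounds) && scrub_mode == "censor")
        extra_confounds <- extra_confounds[!sc$mask$flags, , drop = FALSE]
    }
    m24 <- expand_motion_24(ts$motion)
    if (max(abs(m24)) > 0) confounds <- cbind(confounds, m24)
  }
  if (!is.null(extra_confounds)) confounds <- cbind(confounds, extra_confounds)
  if (!is.null(confounds) && ncol(confounds) > 0)
    ts <- suppressWarnings(nuisance_regress(ts, confounds))
  if (!is.null(band)) ts <- bandpass(ts, band[1], band[2])
  ts
}
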