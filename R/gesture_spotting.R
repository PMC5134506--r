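# Stage-1 gesture spotting. A sport action of interest is flagged wherever
# the arm is elevated AND rotating fast:
#   (elevation > 45 deg) AND (angular-rate magnitude > 400 deg/s)
# Slow elevated motion (e.g. resisted flexion) and fast unelevated motion
# both fail the conjunction, which is what keeps the downstream classifier's
# null class small. Raw per-sample triggers within one refractory period are
# merged into a single detection anchored at the local rate peak.

#' Stage-1 detection rule
#'
#' @param elev_threshold Elevation threshold in degrees (default 45); the
#'   rule requires elevation strictly greater than this.
#' @param rate_threshold Angular-rate magnitude threshold in deg/s (default
#'   400), also a strict inequality.
#' @param refractory Minimum separation between detections in seconds
#'   (default 1.0); runs of raw triggers closer than this merge into one
#'   event.
#' @return An object of class `detection_rule`.
#' @export
detection_rule <- function(elev_threshold = 45, rate_threshold = 400,
                           refractory = 1.0) {
  if (elev_threshold <= 0 || rate_threshold <= 0 || refractory <= 0)
    stop("thresholds and refractory must be positive", call. = FALSE)
  structure(list(elev_threshold = elev_threshold,
                 rate_threshold = rate_threshold,
                 refractory = refractory),
            class = "detection_rule")
}

#' Spot sport-action detections in elevation/rate series
#'
#' Applies the conjunction rule per sample, then merges raw triggers whose
#' successive gaps are all below the refractory period into one detection,
#' anchored at the sample of maximum rate magnitude within the merged run
#' (first such sample on ties). Purely causal up to the refractory lookahead.
#'
#' @param theta Filtered elevation series in degrees (per sample).
#' @param rate_mag Angular-rate magnitude series in deg/s, same length.
#' @param rule A [detection_rule()].
#' @param fs Sampling rate in Hz.
#' @param t Optional sample times; defaults to `(0:(n-1))/fs`.
#' @return A data.frame of class `detection_events` with columns
#'   `index` (anchor sample), `time` (s), `first_index`, `last_index`
#'   (extent of the merged trigger run) and `peak_rate` (deg/s).
#' @examples
#' th <- c(rep(20, 50), rep(90, 10), rep(20, 50))
#' rt <- c(rep(0, 50), rep(900, 10), rep(0, 50))
#' spot_gestures(th, rt, fs = 50)
#' @export
spot_gestures <- function(theta, rate_mag, rule = detection_rule(), fs = 50,
                          t = NULL) {
  n <- length(theta)
  if (length(rate_mag) != n)
    stop("theta and rate_mag must be aligned series of equal length",
         call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  hot <- which(theta > rule$elev_threshold & rate_mag > rule$rate_threshold)
  events <- data.frame(index = integer(), time = numeric(),
                       first_index = integer(), last_index = integer(),
                       peak_rate = numeric())
  if (length(hot)) {
    gap <- rule$refractory * fs
    run_id <- cumsum(c(1L, as.integer(diff(hot) > gap)))
    for (g in split(hot, run_id)) {
      anchor <- g[which.max(rate_mag[g])]
      events <- rbind(events, data.frame(
        index = anchor, time = t[anchor],
        first_index = g[1L], last_index = g[length(g)],
        peak_rate = rate_mag[anchor]))
    }
  }
  rownames(events) <- NULL
  class(events) <- c("detection_events", "data.frame")
  attr(events, "rule") <- rule
  events
}

#' Extract a fixed-width segment around a detection
#'
#' Slices all nine sensor channels plus the per-axis elevation series over
#' the window `[trigger - pre_share * window, trigger + (1 - pre_share) *
#' window)`. At the recording edges the slice is truncated and zero-padded
#' back to nominal length, with `padded = TRUE` flagged.
#'
#' @param rec An [imu_recording()].
#' @param fit The [estimate_orientation()] fit of `rec`.
#' @param index Anchor sample index of the detection (e.g. `events$index[i]`).
#' @param window Window length in seconds (> 0; default 2.0, which holds a
#'   throw's wind-up and follow-through at 50 Hz).
#' @param pre_share Fraction of the window placed before the anchor
#'   (default 0.4).
#' @return An object of class `imu_segment`: list with `accel`, `gyro`,
#'   `mag`, `elev` (nominal-length matrices), `theta`, `rate_mag`, `fs`,
#'   `trigger_offset` (row of the anchor within the window), `padded`.
#' @export
extract_segment <- function(rec, fit, index, window = 2.0, pre_share = 0.4) {
  if (!is.numeric(window) || window <= 0)
    stop("window must be a positive duration in seconds", call. = FALSE)
  if (pre_share < 0 || pre_share > 1)
    stop("pre_share must lie in [0, 1]", call. = FALSE)
  n <- length(rec$t)
  if (index < 1L || index > n)
    stop("detection index outside the recording", call. = FALSE)
  len <- as.integer(round(window * rec$fs))
  pre <- as.integer(round(pre_share * len))
  start <- index - pre
  idx <- start:(start + len - 1L)
  inside <- idx >= 1L & idx <= n
  take <- idx[inside]
  pad_mat <- function(m) {
    out <- matrix(0, len, ncol(m))
    out[inside, ] <- m[take, , drop = FALSE]
    colnames(out) <- colnames(m)
    out
  }
  seg <- structure(list(
    accel = pad_mat(rec$accel),
    gyro = pad_mat(rec$gyro),
    mag = pad_mat(rec$mag),
    elev = pad_mat(fit$elev),
    theta = { v <- numeric(len); v[inside] <- fit$theta[take]; v },
    rate_mag = { v <- numeric(len); v[inside] <- fit$rate_mag[take]; v },
    fs = rec$fs,
    t_start = rec$t[1L] + (start - 1L) / rec$fs,
    trigger_offset = pre + 1L,
    padded = any(!inside)
  ), class = "imu_segment")
  seg
}

#' @export
print.imu_segment <- function(x, ...) {
  cat(sprintf("<imu_segment> %d samples @ %g Hz from %.2f s%s\n",
              length(x$theta), x$fs, x$t_start,
              if (x$padded) " (edge-padded)" else ""))
  invisible(x)
}
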