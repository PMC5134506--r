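# Event-count histograms: a classic histogram over nearest bin centers,
# plus a debounced per-bin event counter. A bin's event counter increments
# only when more than one second (event_spread = 1 x fs samples) has passed
# since the bin was last occupied, so a sustained reach to 150 deg counts
# once, however many samples recorded it.

#' Nearest bin center
#'
#' Index of the bin center closest in absolute distance to `value`; distance
#' ties go to the smallest index, so results do not depend on sort stability.
#'
#' @param value Numeric scalar or vector.
#' @param bin_centers Numeric vector of bin centers in increasing order.
#' @return Integer index (vector) into `bin_centers`.
#' @examples
#' nearest_bin(14, c(0, 10, 20))  # 2
#' nearest_bin(15, c(0, 10, 20))  # 2 (tie between 10 and 20 goes lower)
#' @export
nearest_bin <- function(value, bin_centers) {
  if (!length(bin_centers))
    stop("bin_centers must be non-empty", call. = FALSE)
  if (is.unsorted(bin_centers, strictly = TRUE))
    stop("bin_centers must be strictly increasing", call. = FALSE)
  if (length(bin_centers) == 1L) return(rep(1L, length(value)))
  mids <- (bin_centers[-1L] + bin_centers[-length(bin_centers)]) / 2
  # (mids[j], mids[j+1]] intervals: a value exactly at a midpoint stays in
  # the lower bin
  findInterval(value, mids, left.open = TRUE) + 1L
}

#' Histogram with debounced event counts
#'
#' Assigns every sample of a scalar series to its nearest bin center and
#' accumulates two counts per bin: `histogram`, the classic per-bin sample
#' count, and `event_count`, which increments only when the bin's previous
#' occupancy lies more than `event_spread = 1 * fs` samples in the past. The
#' last-occupancy marker is refreshed on every sample assigned to the bin
#' (not only on counted events), so continuous occupancy never re-counts and
#' a full second of absence is required before a second event is counted.
#' The first occupancy of a bin always counts.
#'
#' @param data Numeric series (length >= 1).
#' @param bin_centers Strictly increasing numeric bin centers.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `event_histogram`: list with `bin_centers`,
#'   `histogram`, `event_count`, `event_spread` (samples), `fs`, `n`.
#' @examples
#' # a 10-s plateau at 10 is one event, not 500
#' h <- hist_and_count(rep(10, 500), c(0, 10, 20), fs = 50)
#' h$histogram    # 0 500 0
#' h$event_count  # 0 1 0
#' @export
hist_and_count <- function(data, bin_centers, fs) {
  if (!length(data)) stop("data must be non-empty", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (any(!is.finite(data))) stop("data must be finite", call. = FALSE)
  nb <- length(bin_centers)
  bins <- nearest_bin(data, bin_centers)
  event_spread <- 1 * fs
  histogram <- tabulate(bins, nbins = nb)
  event_count <- integer(nb)
  for (b in which(histogram > 0L)) {
    idx <- which(bins == b)
    # first occupancy always counts; later ones need a gap > event_spread
    event_count[b] <- 1L + sum(diff(idx) > event_spread)
  }
  structure(list(bin_centers = as.numeric(bin_centers),
                 histogram = histogram,
                 event_count = event_count,
                 event_spread = event_spread,
                 fs = fs,
                 n = length(data)),
            class = "event_histogram")
}

#' @export
print.event_histogram <- function(x, ...) {
  cat(sprintf("<event_histogram> %d samples, %d bins, debounce %g samples\n",
              x$n, length(x$bin_centers), x$event_spread))
  df <- data.frame(center = x$bin_centers, samples = x$histogram,
                   events = x$event_count)
  print(df[df$samples > 0L, , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.event_histogram <- function(x, ...) {
  data.frame(center = x$bin_centers, samples = x$histogram,
             events = x$event_count)
}

#' Default histogram bin centers
#'
#' 20-degree-wide elevation bins centered 10..170 and 150 deg/s-wide rate
#' bins centered 75..2925 (covering the ~2400 deg/s peaks a hard throw
#' reaches).
#'
#' @name default_bins
#' @return Numeric vector of bin centers.
#' @export
default_theta_bins <- function() seq(10, 170, by = 20)

#' @rdname default_bins
#' @export
default_rate_bins <- function() seq(75, 2925, by = 150)

#' Elevation and rate event report for a recording
#'
#' Fuses the recording (unless an [estimate_orientation()] fit is supplied)
#' and applies [hist_and_count()] to the filtered elevation series and to the
#' angular-rate magnitude.
#'
#' @param rec An [imu_recording()].
#' @param cfg A [fusion_config()].
#' @param bins_theta Elevation bin centers in degrees.
#' @param bins_rate Rate-magnitude bin centers in deg/s.
#' @param fit Optional precomputed [estimate_orientation()] fit.
#' @return List with `event_histogram` elements `theta` and `rate`.
#' @export
elevation_event_report <- function(rec, cfg = fusion_config(),
                                   bins_theta = default_theta_bins(),
                                   bins_rate = default_rate_bins(),
                                   fit = NULL) {
  if (is.null(fit)) fit <- estimate_orientation(rec, cfg)
  list(theta = hist_and_count(fit$theta, bins_theta, fit$fs),
       rate = hist_and_count(fit$rate_mag, bins_rate, fit$fs))
}
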