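# Independent oracles kept deliberately naive.

# Literal per-sample transcription of the histogram-and-count pseudocode:
# scan every sample, find the nearest bin by sorting distances, debounce on
# the per-bin last-occupancy index.
hist_count_oracle <- function(data, centers, fs) {
  nb <- length(centers)
  histogram <- integer(nb)
  event_count <- integer(nb)
  spread <- 1 * fs
  last <- rep(-spread - 1, nb)
  for (i in seq_along(data)) {
    distances <- abs(centers - data[i])
    bin <- order(distances)[1L]          # stable: ties to the lowest index
    histogram[bin] <- histogram[bin] + 1L
    if (i - last[bin] > spread)
      event_count[bin] <- event_count[bin] + 1L
    last[bin] <- i
  }
  list(histogram = histogram, event_count = event_count)
}

# Direct-formula Bland-Altman statistics.
bland_altman_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tq <- stats::qt(0.975, n - 1)
  list(mean_diff = m, sd_diff = s,
       ci = c(m - tq * s / sqrt(n), m + tq * s / sqrt(n)),
       loa = c(m - 1.96 * s, m + 1.96 * s),
       r = suppressWarnings(stats::cor(a, b)))  # NA when a count is constant
}

# Angle between two vectors, degrees.
angle_between <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

random_recording <- function(n, fs = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mag <- matrix(rnorm(3 * n, 0, 0.2), n) +
    matrix(rep(c(0.5, 0, -0.85), each = n), n)
  imu_recording(
    accel = matrix(rnorm(3 * n, 0, 0.5), n) +
      matrix(rep(c(1, 0, 0), each = n), n),
    gyro = matrix(rnorm(3 * n, 0, 100), n),
    mag = mag / sqrt(rowSums(mag^2)) * runif(n, 0.8, 1.2),
    fs = fs)
}

# Static hanging-arm recording: device x at nadir, so accel = (1, 0, 0) g
# and the 60-degree-dip field (0.5, 0, -0.866) seen from the device is
# (0.866, 0, 0.5).
static_recording <- function(n, fs = 50) {
  imu_recording(
    accel = matrix(rep(c(1, 0, 0), each = n), n),
    gyro = matrix(0, n, 3),
    mag = matrix(rep(c(0.866, 0, 0.5), each = n), n),
    fs = fs)
}
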