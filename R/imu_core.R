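#' @keywords internal
#' @importFrom randomForest randomForest
#' @importFrom stats predict
"_PACKAGE"

# Channel order used throughout: time, accel xyz (g), gyro xyz (deg/s),
# mag xyz (dimensionless unit-direction).
IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Construct an IMU recording
#'
#' Bundles a uniformly sampled 9-axis sensor stream into an `imu_recording`.
#' The device x-axis points along the arm; a stationary device whose x-axis
#' points at nadir (arm hanging) reads `ax = +1` g, i.e. the accelerometer
#' triplet measures the direction of gravity (nadir) in the device frame.
#' Gyroscope rates are stored sensor-native in degrees per second; the
#' magnetometer is a calibrated unit-direction (norm within \[0.5, 1.5\]).
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   and uniform at rate `fs` (each step within 10% of `1/fs`). If `NULL`,
#'   times `0, 1/fs, 2/fs, ...` are generated.
#' @param accel,gyro,mag Numeric matrices with one row per sample and 3
#'   columns (device x, y, z). Units: g, deg/s, dimensionless.
#' @param fs Sampling rate in Hz (default 50, the logger's native rate).
#' @param meta Optional named list of free-form provenance.
#'
#' @return An object of class `imu_recording`: a list with elements `t`,
#'   `accel`, `gyro`, `mag`, `fs`, `meta`.
#' @examples
#' rec <- imu_recording(accel = matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE),
#'                      gyro  = matrix(0, 5, 3),
#'                      mag   = matrix(rep(c(0, 0.5, -0.87), 5), ncol = 3, byrow = TRUE))
#' rec
#' @export
imu_recording <- function(t = NULL, accel, gyro, mag, fs = 50, meta = list()) {
  accel <- as_sensor_matrix(accel, "accel")
  gyro <- as_sensor_matrix(gyro, "gyro")
  mag <- as_sensor_matrix(mag, "mag")
  n <- nrow(accel)
  if (n < 1L)
    stop("recording must contain at least one sample", call. = FALSE)
  if (nrow(gyro) != n || nrow(mag) != n)
    stop("accel, gyro and mag must have the same number of rows", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  t <- as.numeric(t)
  if (length(t) != n)
    stop("t must have one entry per sample", call. = FALSE)
  rec <- structure(
    list(t = t, accel = accel, gyro = gyro, mag = mag, fs = fs, meta = meta),
    class = "imu_recording"
  )
  validate_imu_recording(rec)
  rec
}

as_sensor_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' Validate an IMU recording's invariants
#'
#' Checks finiteness of all channels, strict monotone uniform sampling
#' (`|dt - 1/fs| < 0.1/fs`) and the calibrated magnetometer norm bound.
#' A recording violating uniform sampling is rejected outright, never
#' silently resampled.
#'
#' @param rec An `imu_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_imu_recording <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  for (ch in c("accel", "gyro", "mag")) {
    bad <- which(!apply(is.finite(rec[[ch]]), 1L, all))
    if (length(bad))
      stop(sprintf("non-finite %s values at sample(s) %s", ch,
                   paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(rec$t)))
    stop("non-finite timestamps", call. = FALSE)
  n <- length(rec$t)
  if (n > 1L) {
    dt <- diff(rec$t)
    if (any(dt <= 0))
      stop(sprintf("timestamps not strictly increasing at sample %d",
                   which(dt <= 0)[1L] + 1L), call. = FALSE)
    nominal <- 1 / rec$fs
    off <- which(abs(dt - nominal) >= 0.1 * nominal)
    if (length(off))
      stop(sprintf("non-uniform sampling at sample %d: dt = %.6g s, expected %.6g s",
                   off[1L] + 1L, dt[off[1L]], nominal), call. = FALSE)
  }
  mnorm <- sqrt(rowSums(rec$mag^2))
  if (any(mnorm < 0.5 | mnorm > 1.5))
    stop(sprintf("magnetometer norm outside [0.5, 1.5] at sample %d",
                 which(mnorm < 0.5 | mnorm > 1.5)[1L]), call. = FALSE)
  invisible(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1L]
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$t), x$fs, dur))
  rate <- sqrt(rowSums(x$gyro^2))
  cat(sprintf("  peak |gyro| %.0f deg/s, accel norm %.2f-%.2f g\n",
              max(rate), min(sqrt(rowSums(x$accel^2))),
              max(sqrt(rowSums(x$accel^2)))))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.imu_recording <- function(x) length(x$t)

#' Read an IMU log file
#'
#' Reads a comma-separated log with one header line and columns
#' `t, ax, ay, az, gx, gy, gz, mx, my, mz` (the time column is optional; when
#' absent, times are generated from `fs`). Lines beginning with `#` are
#' treated as comments. Rows with non-finite sensor values are rejected with
#' their line numbers reported in the error.
#'
#' @param path Path to the log file.
#' @param fs Sampling rate in Hz used to validate (or generate) timestamps.
#' @return An [imu_recording()].
#' @seealso [write_imu_log()]
#' @export
read_imu_log <- function(path, fs = 50) {
  if (!file.exists(path))
    stop(sprintf("log file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  expected <- IMU_CHANNELS
  has_t <- "t" %in% names(df)
  need <- c(if (has_t) "t", expected)
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop(sprintf("malformed log %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[, need, drop = FALSE]
  num <- as.matrix(df[, expected, drop = FALSE])
  storage.mode(num) <- "double"
  bad <- which(!apply(is.finite(num), 1L, all))
  if (length(bad))
    stop(sprintf("non-finite sensor value(s) in %s at data line(s) %s", path,
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  imu_recording(
    t = if (has_t) df$t else NULL,
    accel = num[, 1:3, drop = FALSE],
    gyro = num[, 4:6, drop = FALSE],
    mag = num[, 7:9, drop = FALSE],
    fs = fs,
    meta = list(source = path)
  )
}

#' Write an IMU log file
#'
#' Writes the comma-separated dialect read by [read_imu_log()]: one header
#' line `t,ax,ay,az,gx,gy,gz,mx,my,mz` followed by one row per sample.
#' Optional `comments` are emitted as leading `#` lines (used by the command
#' line tools to embed the generating configuration).
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @param comments Optional character vector of comment lines (without `#`).
#' @param digits Significant digits written (default 7, so a round trip is
#'   faithful to at least 1e-6 on unit-scale channels).
#' @return `path`, invisibly.
#' @export
write_imu_log <- function(rec, path, comments = NULL, digits = 7) {
  validate_imu_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  m <- cbind(rec$t, rec$accel, rec$gyro, rec$mag)
  colnames(m) <- c("t", IMU_CHANNELS)
  writeLines(paste(colnames(m), collapse = ","), con)
  rows <- apply(format(m, digits = digits, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = ",")
  writeLines(rows, con)
  invisible(path)
}

#' Angular-rate magnitude of a recording
#'
#' Euclidean norm of the gyro triplet per sample, in deg/s.
#'
#' @param rec An [imu_recording()].
#' @return Numeric vector, one value per sample.
#' @export
rate_magnitude <- function(rec) {
  sqrt(rowSums(rec$gyro^2))
}
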