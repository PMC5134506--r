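# AHRS sensor fusion and arm-elevation estimation.
#
# Elevation theta is the angle between the device x-axis (along the arm) and
# nadir (0, 0, -1) in a z-up world frame: 0 deg = arm hanging, 180 deg = arm
# straight overhead. Two estimators are provided: the accelerometer-only
# angle acos(ax / |a|), which is corrupted whenever linear acceleration is
# superimposed on gravity (throws), and the filtered angle derived from the
# fused orientation, which tolerates shocks because the gyro propagates the
# attitude through them.

#' Fusion filter configuration
#'
#' Settings for the quaternion attitude-and-heading (AHRS) filter. The filter
#' propagates the orientation with the rate gyroscope and applies a
#' normalized gradient-descent correction toward the accelerometer (gravity)
#' and magnetometer (North) reference directions. `gain` is the correction
#' step magnitude in rad/s; it bounds both the convergence rate and the
#' gyro-bias drift the filter can absorb. The magnetometer only constrains
#' heading (rotation about the gravity axis), so magnetic distortion cannot
#' corrupt the elevation estimate; set `use_mag = FALSE` to run gravity-only.
#'
#' @param gain Correction gain in rad/s (default 0.1).
#' @param use_mag Use the magnetometer heading correction (default TRUE).
#' @param init Initial state policy: `"triad"` aligns the first state with the
#'   first accelerometer + magnetometer sample; `"identity"` starts at the
#'   identity orientation.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(gain = 0.1, use_mag = TRUE,
                          init = c("triad", "identity")) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain < 0)
    stop("gain must be a single finite number >= 0", call. = FALSE)
  structure(list(gain = gain, use_mag = isTRUE(use_mag),
                 init = match.arg(init)),
            class = "fusion_config")
}

#' Orientation state
#'
#' A unit quaternion device-to-world attitude estimate with its direction
#' cosine matrix (DCM). `DCM %*% v_device` expresses a device-frame vector in
#' the world frame (z up, x toward magnetic North's horizontal projection).
#'
#' @param q Numeric length-4 quaternion `(w, x, y, z)`; normalized on input.
#' @param t Time in seconds.
#' @return An object of class `orientation_state` with fields `q`, `t`, `DCM`.
#' @export
orientation_state <- function(q, t = 0) {
  if (length(q) != 4L || any(!is.finite(q)))
    stop("q must be a finite length-4 quaternion", call. = FALSE)
  q <- quat_normalize(as.numeric(q))
  structure(list(q = q, t = t, DCM = quat_to_dcm(q)),
            class = "orientation_state")
}

#' @export
print.orientation_state <- function(x, ...) {
  cat(sprintf("<orientation_state> t = %.3f s, q = (%.4f, %.4f, %.4f, %.4f)\n",
              x$t, x$q[1], x$q[2], x$q[3], x$q[4]))
  cat(sprintf("  elevation %.1f deg\n", elevation_from_state(x)))
  invisible(x)
}

#' Accelerometer-only arm elevation
#'
#' `theta = acos(ax / |a|)` in degrees: the angle between the device x-axis
#' (along the arm) and the measured acceleration direction, which equals the
#' arm-to-nadir angle only while the accelerometer senses gravity alone.
#'
#' @param accel Numeric 3-vector, or an n-by-3 matrix (one row per sample),
#'   in g.
#' @return Elevation angle(s) in degrees, clamped into \[0, 180\].
#' @examples
#' elevation_from_accel(c(1, 0, 0))        # arm hanging: 0
#' elevation_from_accel(c(0, 1, 0))        # horizontal: 90
#' @export
elevation_from_accel <- function(accel) {
  if (!is.matrix(accel)) accel <- matrix(accel, 1L)
  nrm <- sqrt(rowSums(accel^2))
  if (any(nrm <= 1e-6))
    stop("acceleration norm too small: elevation angle undefined", call. = FALSE)
  th <- acos(pmin(1, pmax(-1, accel[, 1L] / nrm))) * 180 / pi
  pmin(180, pmax(0, th))
}

#' Arm elevation from a fused orientation state
#'
#' Rotates the device x-axis into the world frame with the DCM and returns
#' its angle to nadir: `acos((DCM \%*\% (1,0,0)) . (0,0,-1))` in degrees. The
#' dot product is clamped into \[-1, 1\] before the arccosine.
#'
#' @param state An [orientation_state()].
#' @return Elevation in degrees in \[0, 180\].
#' @export
elevation_from_state <- function(state) {
  stopifnot(inherits(state, "orientation_state"))
  d <- -state$DCM[3L, 1L]  # (DCM e1) . (0,0,-1)
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

# TRIAD-style initial attitude from one accelerometer + magnetometer sample.
# accel measures the nadir direction in the device frame (ax = +1 g when the
# arm hangs); mag measures the (dip-tilted) field direction.
triad_init <- function(accel, mag) {
  d <- accel / sqrt(sum(accel^2))          # nadir, device frame
  m <- mag / sqrt(sum(mag^2))
  n <- m - sum(m * d) * d                  # horizontal North, device frame
  nn <- sqrt(sum(n * n))
  if (nn < 1e-6) n <- cross3(d, c(0, 1, 0)) else n <- n / nn
  up <- -d
  east <- cross3(up, n)
  # rows of the device->world DCM are the world axes in device coordinates
  R <- rbind(n, east, up)
  dimnames(R) <- NULL
  dcm_to_quat(R)
}

# One fused update of q over dt. Gyro in deg/s, accel in g (nadir-positive
# convention), mag a unit direction. The correction is a normalized
# gradient-descent step of magnitude `gain` (rad/s) on the combined
# gravity + magnetic alignment objective f(q) = R(q)^T v_ref - v_meas.
madgwick_update <- function(q, gyro_deg, accel, mag, dt, gain, use_mag = TRUE) {
  omega <- gyro_deg * (pi / 180)
  # exact exponential propagation: q <- q x exp((0, omega) dt / 2); at the
  # ~2000 deg/s reached mid-throw a first-order Euler step would lose
  # degrees per sample, the closed form does not
  ang <- sqrt(sum(omega^2)) * dt
  if (ang > 1e-12) {
    u <- omega * (dt / ang)
    h <- ang / 2
    dq <- c(cos(h), u * sin(h))
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    q <- c(w * dq[1L] - x * dq[2L] - y * dq[3L] - z * dq[4L],
           w * dq[2L] + x * dq[1L] + y * dq[4L] - z * dq[3L],
           w * dq[3L] - x * dq[4L] + y * dq[1L] + z * dq[2L],
           w * dq[4L] + x * dq[3L] - y * dq[2L] + z * dq[1L])
  }
  qd <- c(0, 0, 0, 0)
  if (gain > 0) {
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    an <- sqrt(sum(accel^2))
    if (is.finite(an) && an > 1e-6) {
      r <- c(x, y, z)
      # accel points at nadir; flip so the reference is world "up" (0,0,1)
      am <- -accel / an
      s <- grad_body_align(w, r, c(0, 0, 1), am)
      if (use_mag) {
        mn <- sqrt(sum(mag^2))
        if (is.finite(mn) && mn > 1e-6) {
          mh <- mag / mn
          h <- quat_rotate(q, mh)
          b <- c(sqrt(h[1L]^2 + h[2L]^2), 0, h[3L])
          s <- s + grad_body_align(w, r, b, mh)
        }
      }
      sn <- sqrt(sum(s * s))
      if (sn > 1e-12) qd <- qd - gain * (s / sn)
    }
  }
  quat_normalize(q + qd * dt)
}

# Gradient (w.r.t. q) of 0.5 * |R(q)^T v - meas|^2, i.e. J^T f, where
# R(q)^T v = v - 2 w (r x v) + 2 r x (r x v).
grad_body_align <- function(w, r, v, meas) {
  rxv <- c(r[2L] * v[3L] - r[3L] * v[2L],
           r[3L] * v[1L] - r[1L] * v[3L],
           r[1L] * v[2L] - r[2L] * v[1L])
  rxrxv <- c(r[2L] * rxv[3L] - r[3L] * rxv[2L],
             r[3L] * rxv[1L] - r[1L] * rxv[3L],
             r[1L] * rxv[2L] - r[2L] * rxv[1L])
  f <- v - 2 * w * rxv + 2 * rxrxv - meas
  # d/dw = -2 (r x v); d/dr = 2 w [v]x + 2 (r v^T + (r.v) I - 2 v r^T)
  gw <- -2 * sum(rxv * f)
  rv <- sum(r * v)
  # [v]x f = v x f
  vxf <- c(v[2L] * f[3L] - v[3L] * f[2L],
           v[3L] * f[1L] - v[1L] * f[3L],
           v[1L] * f[2L] - v[2L] * f[1L])
  # (d/dr)^T f = -2 w (v x f) + 2 ( v (r.f) + (r.v) f - 2 r (v.f) )
  gr <- -2 * w * vxf + 2 * (v * sum(r * f) + rv * f - 2 * r * sum(v * f))
  c(gw, gr)
}

#' Advance the AHRS filter by one sample
#'
#' Propagates the quaternion by the gyro rate over `dt`, applies the
#' gravity + North correction step scaled by the configured gain, and
#' renormalizes.
#'
#' @param state An [orientation_state()].
#' @param sample A list with numeric 3-vectors `accel` (g), `gyro` (deg/s)
#'   and `mag` (unit direction).
#' @param dt Time step in seconds (> 0).
#' @param cfg A [fusion_config()].
#' @return The updated [orientation_state()] at `state$t + dt`.
#' @export
ahrs_step <- function(state, sample, dt, cfg = fusion_config()) {
  stopifnot(inherits(state, "orientation_state"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  vals <- c(sample$accel, sample$gyro, sample$mag)
  if (length(vals) != 9L || any(!is.finite(vals)))
    stop("sample must carry finite accel, gyro and mag 3-vectors", call. = FALSE)
  q <- madgwick_update(state$q, sample$gyro, sample$accel, sample$mag,
                       dt, cfg$gain, cfg$use_mag)
  orientation_state(q, state$t + dt)
}

#' Fuse a whole recording into orientation and elevation series
#'
#' Runs the AHRS filter over every sample of the recording and returns the
#' per-sample quaternion, the filtered arm elevation, the accelerometer-only
#' elevation, the angular-rate magnitude, and the elevation of each device
#' axis relative to gravity (used downstream as classifier features).
#'
#' @param rec An [imu_recording()].
#' @param cfg A [fusion_config()].
#' @return An object of class `orientation_fit`: a list with `t`, `q`
#'   (n-by-4 matrix), `theta` (filtered elevation, deg), `theta_accel`
#'   (accelerometer-only, deg), `rate_mag` (deg/s), `elev` (n-by-3 per-axis
#'   elevation, deg), `fs`, and `cfg`.
#' @examples
#' rec <- generate_session(session_script(list(rest = 1), seed = 1),
#'                         noise = sensor_noise(gyro_sd = 0, accel_sd = 0,
#'                                              mag_sd = 0, gyro_bias_max = 0))$recording
#' fit <- estimate_orientation(rec)
#' range(fit$theta)
#' @export
estimate_orientation <- function(rec, cfg = fusion_config()) {
  validate_imu_recording(rec)
  n <- length(rec$t)
  qs <- matrix(0, n, 4L)
  q <- if (cfg$init == "triad") triad_init(rec$accel[1L, ], rec$mag[1L, ])
       else c(1, 0, 0, 0)
  qs[1L, ] <- q
  if (n > 1L) {
    dts <- diff(rec$t)
    accel <- rec$accel; gyro <- rec$gyro; mag <- rec$mag
    gain <- cfg$gain; use_mag <- cfg$use_mag
    for (i in 2:n) {
      q <- madgwick_update(q, gyro[i, ], accel[i, ], mag[i, ],
                           dts[i - 1L], gain, use_mag)
      qs[i, ] <- q
    }
  }
  # z-row of each DCM: world-z component of the device axes
  w <- qs[, 1L]; x <- qs[, 2L]; y <- qs[, 3L]; z <- qs[, 4L]
  zrow <- cbind(2 * (x * z - w * y),
                2 * (y * z + w * x),
                w^2 - x^2 - y^2 + z^2)
  elev <- matrix(acos(pmin(1, pmax(-1, -zrow))) * 180 / pi, n, 3L,
                 dimnames = list(NULL, c("x", "y", "z")))
  structure(list(
    t = rec$t,
    q = qs,
    theta = elev[, 1L],
    theta_accel = elevation_from_accel(rec$accel),
    rate_mag = rate_magnitude(rec),
    elev = elev,
    fs = rec$fs,
    cfg = cfg
  ), class = "orientation_fit")
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf("<orientation_fit> %d samples @ %g Hz, gain %g rad/s\n",
              length(x$t), x$fs, x$cfg$gain))
  cat(sprintf("  elevation %.1f-%.1f deg, peak rate %.0f deg/s\n",
              min(x$theta), max(x$theta), max(x$rate_mag)))
  invisible(x)
}
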