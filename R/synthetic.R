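# Ground-truthed simulator of arm-worn IMU sessions.
#
# The arm's orientation is modelled directly as a time-parameterized
# device->world rotation q(t) = Rz(psi) Ry(90deg - alpha) Rx(phi), where
# alpha is the arm elevation (0 = hanging, 180 = overhead), phi the rotation
# about the arm's long axis (internal/external rotation) and psi the compass
# heading. Each activity repetition is a set of keyframes per channel,
# joined by minimum-jerk segments (zero velocity and acceleration at every
# keyframe, so q(t) is twice differentiable and the angular rate is
# continuous). Sensors are derived analytically from q(t):
#   gyro  = body angular rate of q(t) (quaternion finite difference at a
#           1 ms half-step) + white noise + a constant per-axis bias,
#   accel = device-frame nadir direction (1 g, the rest-pose convention)
#           + short Gaussian-bell linear-acceleration impulses at ball
#           release / contact + white noise,
#   mag   = device-frame Earth field direction (60 deg dip) + white noise.
# Throws are internal-rotation-dominant (fast about device x), serves are
# elevation-plane-dominant (about device y/z) and slower, so the two sports
# differ in both rotation axis and spectral band content; the seven resisted
# exercises keep elevated-phase rates below ~350 deg/s so they never pass
# the 45 deg / 400 deg/s stage-1 rule, and "rest" holds the base pose.

REST_ALPHA <- 10  # hanging-arm elevation, deg

# Minimum-jerk interpolation through keyframes (matrix columns t, v);
# constant extrapolation outside the keyframe range.
minjerk_interp <- function(kt, kv, t) {
  n <- length(kt)
  i <- findInterval(t, kt)
  i <- pmin(pmax(i, 1L), n - 1L)
  tau <- (t - kt[i]) / (kt[i + 1L] - kt[i])
  tau <- pmin(pmax(tau, 0), 1)
  s <- tau^3 * (10 - 15 * tau + 6 * tau^2)
  kv[i] + (kv[i + 1L] - kv[i]) * s
}

# Activity templates: per-rep keyframes as (time fraction, value in deg).
# `alpha` values scale about REST_ALPHA with the rep intensity; `phi` scales
# about 0. `lin` lists linear-acceleration impulses (time fraction,
# amplitude g, width s, device-frame direction).
activity_template_list <- function() {
  list(
    baseball_throw = list(
      duration = 1.6,
      alpha = rbind(c(0, REST_ALPHA), c(0.30, 120), c(0.52, 150),
                    c(0.70, 90), c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(0.35, -90), c(0.50, 180), c(0.72, 20), c(1, 0)),
      lin = list(list(at = 0.51, amp = 3.5, width = 0.05,
                      dir = c(-0.8, 0.4, 0.45))),
      sport = TRUE),
    volleyball_serve = list(
      duration = 1.9,
      alpha = rbind(c(0, 12), c(0.35, 70), c(0.50, 165), c(0.57, 80),
                    c(1, 12)),
      phi = rbind(c(0, 0), c(0.40, -30), c(0.60, 25), c(1, 0)),
      lin = list(list(at = 0.54, amp = 2.5, width = 0.07,
                      dir = c(-0.5, -0.3, 0.8))),
      sport = TRUE),
    external_rotation_90 = list(
      duration = 3.0,
      alpha = rbind(c(0, REST_ALPHA), c(0.25, 88), c(0.75, 88),
                    c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(0.30, -10), c(0.50, -75), c(0.70, -10),
                  c(1, 0)),
      lin = list(), sport = FALSE),
    throw_deceleration = list(
      duration = 2.5,
      alpha = rbind(c(0, REST_ALPHA), c(0.30, 110), c(0.55, 130),
                    c(0.80, 60), c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(0.35, -50), c(0.62, 30), c(1, 0)),
      lin = list(), sport = FALSE),
    throw_acceleration = list(
      duration = 2.5,
      alpha = rbind(c(0, REST_ALPHA), c(0.30, 100), c(0.50, 125),
                    c(0.75, 55), c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(0.30, -45), c(0.58, 35), c(1, 0)),
      lin = list(), sport = FALSE),
    flexion = list(
      duration = 3.2,
      alpha = rbind(c(0, REST_ALPHA), c(0.45, 165), c(0.55, 165),
                    c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(1, 0)),
      lin = list(), sport = FALSE),
    extension = list(
      duration = 2.2,
      alpha = rbind(c(0, REST_ALPHA), c(0.20, 40), c(0.50, 5),
                    c(0.80, 40), c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(1, 0)),
      lin = list(), sport = FALSE),
    external_rotation_side = list(
      duration = 2.8,
      alpha = rbind(c(0, REST_ALPHA), c(0.20, 18), c(0.80, 18),
                    c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(0.30, 60), c(0.70, 0), c(1, 0)),
      lin = list(), sport = FALSE),
    scapular_punch = list(
      duration = 2.0,
      alpha = rbind(c(0, REST_ALPHA), c(0.30, 80), c(0.70, 80),
                    c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(1, 0)),
      lin = list(list(at = 0.42, amp = 0.8, width = 0.08,
                      dir = c(0, 0.9, 0.44)),
                 list(at = 0.60, amp = 0.8, width = 0.08,
                      dir = c(0, -0.9, -0.44))),
      sport = FALSE),
    rest = list(
      duration = 4.0,
      alpha = rbind(c(0, REST_ALPHA), c(1, REST_ALPHA)),
      phi = rbind(c(0, 0), c(1, 0)),
      lin = list(), sport = FALSE)
  )
}

#' Available activity templates
#'
#' @return Character vector of activity names the simulator understands: the
#'   two sports, the seven resisted shoulder exercises, and rest.
#' @export
activity_templates <- function() names(activity_template_list())

#' Sensor noise and bias configuration
#'
#' Defaults are plausible for consumer MEMS parts: 1 deg/s rms gyro white
#' noise with a constant per-axis bias drawn uniformly within +/- 2 deg/s,
#' 0.02 g rms accelerometer noise, 0.005 magnetometer noise. `clip_dps`
#' enables per-axis gyro full-scale saturation (e.g. 2000 deg/s); it is off
#' (`Inf`) by default so the ~2400 deg/s rate-magnitude peaks of a hard
#' throw remain reachable through multi-axis composition.
#'
#' @param gyro_sd Gyro white-noise sd, deg/s.
#' @param accel_sd Accelerometer white-noise sd, g.
#' @param mag_sd Magnetometer white-noise sd (dimensionless).
#' @param gyro_bias_max Per-axis constant gyro bias bound, deg/s.
#' @param clip_dps Per-axis gyro saturation limit, deg/s (`Inf` = off).
#' @return An object of class `sensor_noise`.
#' @export
sensor_noise <- function(gyro_sd = 1, accel_sd = 0.02, mag_sd = 0.005,
                         gyro_bias_max = 2, clip_dps = Inf) {
  structure(list(gyro_sd = gyro_sd, accel_sd = accel_sd, mag_sd = mag_sd,
                 gyro_bias_max = gyro_bias_max, clip_dps = clip_dps),
            class = "sensor_noise")
}

#' Session script
#'
#' An ordered plan of activities with repetition counts, driving
#' [generate_session()]. Gaps are generous enough (>= 1 s) that ground-truth
#' events stay separable under the one-second debounce rule.
#'
#' @param activities Named list or named integer vector: activity name (see
#'   [activity_templates()]) -> number of repetitions, in performance order.
#' @param seed Integer seed; all randomness of the session (rep intensities,
#'   gap jitter, headings, sensor noise) flows from it.
#' @param subject_scale Kinematic scale of this subject (amplitudes and hence
#'   rates), e.g. 0.85-1.15 across a panel of throwers.
#' @param rep_gap Nominal pause between repetitions, s (>= 1).
#' @param rest_gap Nominal pause between activities, s (>= 1).
#' @return An object of class `session_script`.
#' @export
session_script <- function(activities, seed = 1, subject_scale = 1,
                           rep_gap = 1.4, rest_gap = 3.0) {
  reps <- as.integer(unlist(activities))
  names(reps) <- names(activities)
  unknown <- setdiff(names(reps), activity_templates())
  if (length(unknown))
    stop(sprintf("unknown activity template(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (any(reps < 1L))
    stop("repetitions must be >= 1", call. = FALSE)
  if (rep_gap < 1 || rest_gap < 1)
    stop("gaps must be >= 1 s so events remain separable", call. = FALSE)
  structure(list(activities = reps, seed = as.integer(seed),
                 subject_scale = subject_scale,
                 rep_gap = rep_gap, rest_gap = rest_gap),
            class = "session_script")
}

#' @export
print.session_script <- function(x, ...) {
  cat(sprintf("<session_script> seed %d, subject scale %.2f\n",
              x$seed, x$subject_scale))
  cat(paste(sprintf("  %s x%d", names(x$activities), x$activities),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Generate a synthetic IMU session with ground truth
#'
#' Builds the session's orientation trajectory from the script's activity
#' templates, derives the three sensor streams analytically, applies the
#' noise model, and returns the recording together with its ground truth.
#'
#' @param script A [session_script()].
#' @param noise A [sensor_noise()] configuration.
#' @param fs Sampling rate in Hz (default 50).
#' @return A list with
#'   `recording` (an [imu_recording()]),
#'   `truth` (list: `events` data.frame with one row per repetition --
#'   activity, onset s, peak_time s, peak_rate deg/s, sport flag; `counts`
#'   named vector of repetitions per activity; `q` the true n-by-4
#'   quaternion series; `theta` the true elevation series, deg).
#' @examples
#' s <- session_script(list(baseball_throw = 2, rest = 1), seed = 7)
#' out <- generate_session(s)
#' out$truth$counts
#' @export
generate_session <- function(script, noise = sensor_noise(), fs = 50) {
  stopifnot(inherits(script, "session_script"))
  tpl <- activity_template_list()
  set.seed(script$seed)

  ka_t <- 0; ka_v <- REST_ALPHA     # alpha keyframes
  kp_t <- 0; kp_v <- 0              # phi keyframes
  kh_t <- 0; kh_v <- 0              # psi (heading) keyframes
  impulses <- list()
  events <- list()
  cursor <- 1.0
  psi_now <- 0

  for (ai in seq_along(script$activities)) {
    act <- names(script$activities)[ai]
    reps <- script$activities[[ai]]
    tp <- tpl[[act]]
    # heading transition during the preceding gap (low elevation, slow);
    # rest keeps the current heading so rest-only scripts are truly static
    psi_new <- if (act == "rest") psi_now else stats::runif(1, -60, 60)
    kh_t <- c(kh_t, cursor - 0.15, cursor + script$rest_gap * 0.55)
    kh_v <- c(kh_v, psi_now, psi_new)
    psi_now <- psi_new
    cursor <- cursor + script$rest_gap
    for (r in seq_len(reps)) {
      intensity <- script$subject_scale *
        min(1.2, max(0.8, stats::rnorm(1, 1, 0.08)))
      D <- tp$duration
      t0 <- cursor
      a_t <- t0 + tp$alpha[, 1L] * D
      a_v <- REST_ALPHA + (tp$alpha[, 2L] - REST_ALPHA) * intensity
      p_t <- t0 + tp$phi[, 1L] * D
      p_v <- tp$phi[, 2L] * intensity
      ka_t <- c(ka_t, a_t); ka_v <- c(ka_v, a_v)
      kp_t <- c(kp_t, p_t); kp_v <- c(kp_v, p_v)
      for (im in tp$lin)
        impulses[[length(impulses) + 1L]] <-
          list(t = t0 + im$at * D, amp = im$amp * intensity,
               width = im$width, dir = im$dir)
      events[[length(events) + 1L]] <-
        data.frame(activity = act, onset = t0, duration = D,
                   sport = isTRUE(tp$sport))
      cursor <- cursor + D + script$rep_gap * stats::runif(1, 0.9, 1.2)
    }
  }
  total <- cursor + 2.0
  n <- as.integer(ceiling(total * fs))
  t <- (seq_len(n) - 1L) / fs

  # drop duplicate keyframe times (rep boundaries meeting holds)
  dedup <- function(kt, kv) {
    o <- order(kt)
    kt <- kt[o]; kv <- kv[o]
    keep <- c(TRUE, diff(kt) > 1e-9)
    list(t = c(kt[keep], total + 1), v = c(kv[keep], kv[length(kv)]))
  }
  ka <- dedup(ka_t, ka_v); kp <- dedup(kp_t, kp_v); kh <- dedup(kh_t, kh_v)

  q_at <- function(tt) {
    alpha <- minjerk_interp(ka$t, ka$v, tt) * pi / 180
    phi <- minjerk_interp(kp$t, kp$v, tt) * pi / 180
    psi <- minjerk_interp(kh$t, kh$v, tt) * pi / 180
    beta <- pi / 2 - alpha
    qz <- cbind(cos(psi / 2), 0, 0, sin(psi / 2))
    qy <- cbind(cos(beta / 2), 0, sin(beta / 2), 0)
    qx <- cbind(cos(phi / 2), sin(phi / 2), 0, 0)
    quat_multiply(quat_multiply(qz, qy), qx)
  }
  q <- q_at(t)
  if (!is.matrix(q)) q <- matrix(q, 1L)

  # body angular rate from the quaternion derivative: (0, w) = 2 q^-1 qdot
  delta <- 1e-3
  qdot <- (q_at(t + delta) - q_at(t - delta)) / (2 * delta)
  if (!is.matrix(qdot)) qdot <- matrix(qdot, 1L)
  wq <- quat_multiply(quat_conjugate(q), qdot)
  if (!is.matrix(wq)) wq <- matrix(wq, 1L)
  gyro_true <- 2 * wq[, 2:4, drop = FALSE] * 180 / pi

  # accelerometer: device-frame nadir + linear-acceleration impulses
  qc <- quat_conjugate(q)
  accel_true <- quat_rotate(qc, c(0, 0, -1))
  if (!is.matrix(accel_true)) accel_true <- matrix(accel_true, 1L)
  for (im in impulses) {
    sel <- which(abs(t - im$t) < 4 * im$width)
    if (!length(sel)) next
    bump <- im$amp * exp(-0.5 * ((t[sel] - im$t) / im$width)^2)
    accel_true[sel, ] <- accel_true[sel, ] +
      outer(bump, im$dir / sqrt(sum(im$dir^2)))
  }

  dip <- 60 * pi / 180
  mag_true <- quat_rotate(qc, c(cos(dip), 0, -sin(dip)))
  if (!is.matrix(mag_true)) mag_true <- matrix(mag_true, 1L)

  bias <- stats::runif(3, -noise$gyro_bias_max, noise$gyro_bias_max)
  gyro <- gyro_true + matrix(stats::rnorm(3 * n, 0, noise$gyro_sd), n) +
    matrix(bias, n, 3L, byrow = TRUE)
  if (is.finite(noise$clip_dps))
    gyro <- pmin(pmax(gyro, -noise$clip_dps), noise$clip_dps)
  accel <- accel_true + matrix(stats::rnorm(3 * n, 0, noise$accel_sd), n)
  mag <- mag_true + matrix(stats::rnorm(3 * n, 0, noise$mag_sd), n)

  rec <- imu_recording(t = t, accel = accel, gyro = gyro, mag = mag, fs = fs,
                       meta = list(seed = script$seed,
                                   subject_scale = script$subject_scale))

  ev <- do.call(rbind, events)
  rate_true <- sqrt(rowSums(gyro_true^2))
  ev$peak_time <- NA_real_; ev$peak_rate <- NA_real_
  for (i in seq_len(nrow(ev))) {
    sel <- which(t >= ev$onset[i] & t <= ev$onset[i] + ev$duration[i])
    j <- sel[which.max(rate_true[sel])]
    ev$peak_time[i] <- t[j]
    ev$peak_rate[i] <- rate_true[j]
  }
  counts <- table(factor(ev$activity, levels = names(script$activities)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  # elevation of device x-axis: acos( (R e1) . (0,0,-1) ) = acos(-R[3,1])
  theta_true <- acos(pmin(1, pmax(-1,
    -2 * (q[, 2L] * q[, 4L] - q[, 1L] * q[, 3L])))) * 180 / pi

  # 4x-oversampled true trajectory: lets consumers differentiate q(t)
  # numerically at a resolution where the fast sport swings are resolved
  over <- 4L
  t_fine <- (seq_len(n * over) - 1L) / (fs * over)
  q_fine <- q_at(t_fine)
  if (!is.matrix(q_fine)) q_fine <- matrix(q_fine, 1L)

  list(recording = rec,
       truth = list(events = ev, counts = counts, q = q, theta = theta_true,
                    gyro_true = gyro_true, bias = bias,
                    q_fine = q_fine, fs_fine = fs * over))
}

#' Benchmark suite of control and randomized session scripts
#'
#' Mirrors a two-session protocol per subject: a control session performing
#' each activity for a fixed eight repetitions in a fixed order, then a
#' randomized session with shuffled activity order, 2-6 repetitions per
#' exercise and 4-12 repetitions per sport, all drawn per subject. Each
#' simulated subject also carries a +/- 15% kinematic scale emulating varying
#' throwing experience.
#'
#' @param seed Integer master seed; per-subject seeds derive from it.
#' @param n_subjects Number of simulated subjects (default 11).
#' @return List with `control` and `randomized`, each a list of
#'   `n_subjects` [session_script()]s.
#' @export
default_benchmark_suite <- function(seed = 1, n_subjects = 11) {
  base <- abs(as.integer(seed)) %% 100000L
  exercises <- setdiff(activity_templates(), c("baseball_throw",
                                               "volleyball_serve", "rest"))
  control <- vector("list", n_subjects)
  randomized <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(base * 131L + i)
    scale <- stats::runif(1, 0.85, 1.15)
    ctrl_acts <- as.list(stats::setNames(
      rep(8L, length(exercises) + 2L),
      c(exercises, "baseball_throw", "volleyball_serve")))
    control[[i]] <- session_script(ctrl_acts, seed = base * 10000L + i,
                                   subject_scale = scale)
    order9 <- sample(c(exercises, "baseball_throw", "volleyball_serve"))
    reps <- vapply(order9, function(a)
      if (a %in% c("baseball_throw", "volleyball_serve"))
        sample(4:12, 1L) else sample(2:6, 1L), integer(1L))
    randomized[[i]] <- session_script(as.list(reps),
                                      seed = base * 10000L + 5000L + i,
                                      subject_scale = scale)
  }
  list(control = control, randomized = randomized)
}
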