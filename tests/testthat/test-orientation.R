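test_that("accelerometer-only elevation follows acos(ax/|a|)", {
  expect_equal(elevation_from_accel(c(1, 0, 0)), 0)
  expect_equal(elevation_from_accel(c(0, 1, 0)), 90)
  expect_equal(elevation_from_accel(c(0.5, 0.8660254, 0)), 60, tolerance = 1e-6)
  expect_equal(elevation_from_accel(c(-1, 0, 0)), 180)
  # magnitude-invariant
  expect_equal(elevation_from_accel(c(0.2, 0.3, -0.1)),
               elevation_from_accel(10 * c(0.2, 0.3, -0.1)))
  expect_error(elevation_from_accel(c(0, 0, 0)), "undefined")
})

test_that("state elevation equals the angle between world x-image and nadir", {
  expect_equal(elevation_from_state(orientation_state(c(1, 0, 0, 0))), 90)
  # device x rotated onto nadir
  q_down <- armspot:::quat_from_axis_angle(c(0, 1, 0), pi / 2)
  expect_equal(elevation_from_state(orientation_state(q_down)), 0,
               tolerance = 1e-9)
  set.seed(31)
  for (i in 1:200) {
    q <- armspot:::quat_normalize(rnorm(4))
    st <- orientation_state(q)
    oracle <- angle_between(st$DCM %*% c(1, 0, 0), c(0, 0, -1))
    expect_equal(elevation_from_state(st), oracle, tolerance = 1e-9)
  }
})

test_that("orientation states carry orthonormal DCMs and unit quaternions", {
  set.seed(5)
  for (i in 1:50) {
    st <- orientation_state(rnorm(4))
    expect_equal(sum(st$q^2), 1, tolerance = 1e-12)
    expect_equal(crossprod(st$DCM), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(det(st$DCM), 1, tolerance = 1e-8)
  }
})

test_that("a static aligned state is a fixed point of the filter", {
  rec <- static_recording(10)
  st <- orientation_state(armspot:::triad_init(rec$accel[1, ], rec$mag[1, ]))
  sample <- list(accel = rec$accel[1, ], gyro = c(0, 0, 0),
                 mag = rec$mag[1, ])
  for (i in 1:100) st <- ahrs_step(st, sample, 0.02)
  expect_equal(elevation_from_state(st), 0, tolerance = 1e-6)
  expect_equal(sum(st$q^2), 1, tolerance = 1e-9)
})

test_that("gyro-only integration matches the closed-form axis-angle rotation", {
  cfg <- fusion_config(gain = 0)
  # 90 deg/s about device z for exactly 1 s at 50 Hz
  st <- orientation_state(c(1, 0, 0, 0))
  smp <- list(accel = c(1, 0, 0), gyro = c(0, 0, 90), mag = c(0.87, 0, 0.5))
  for (i in 1:50) st <- ahrs_step(st, smp, 0.02, cfg)
  q_exact <- armspot:::quat_from_axis_angle(c(0, 0, 1), pi / 2)
  err <- 2 * acos(min(1, abs(sum(st$q * q_exact)))) * 180 / pi
  expect_lt(err, 0.1)
  # arbitrary fixed axis, 90 degrees rotated: error below 0.2 deg
  set.seed(8)
  for (k in 1:5) {
    axis <- armspot:::quat_normalize(rnorm(3) + 1e-3)[1:3]
    axis <- axis / sqrt(sum(axis^2))
    rate <- 90  # deg/s
    st <- orientation_state(c(1, 0, 0, 0))
    for (i in 1:50) st <- ahrs_step(st, list(accel = c(1, 0, 0),
                                             gyro = axis * rate,
                                             mag = c(0.87, 0, 0.5)), 0.02, cfg)
    q_exact <- armspot:::quat_from_axis_angle(axis, pi / 2)
    err <- 2 * acos(min(1, abs(sum(st$q * q_exact)))) * 180 / pi
    expect_lt(err, 0.2)
  }
})

test_that("quaternions stay unit-norm through noisy updates", {
  set.seed(9)
  st <- orientation_state(c(1, 0, 0, 0))
  for (i in 1:300) {
    st <- ahrs_step(st, list(accel = rnorm(3, c(1, 0, 0), 0.3),
                             gyro = rnorm(3, 0, 400),
                             mag = c(0.87, 0, 0.5) + rnorm(3, 0, 0.05)),
                    0.02)
    expect_equal(sum(st$q^2), 1, tolerance = 1e-9)
  }
  expect_error(ahrs_step(st, list(accel = c(NA, 0, 0), gyro = c(0, 0, 0),
                                  mag = c(0.87, 0, 0.5)), 0.02), "finite")
  expect_error(ahrs_step(st, list(accel = c(1, 0, 0), gyro = c(0, 0, 0),
                                  mag = c(0.87, 0, 0.5)), 0), "dt")
})

test_that("the correction step descends the alignment objective", {
  # analytic gradient agrees with a numerical one, so the correction moves
  # the estimate toward the measured gravity/North directions
  set.seed(13)
  for (i in 1:20) {
    q <- armspot:::quat_normalize(rnorm(4))
    v <- armspot:::quat_normalize(rnorm(4))[2:4]
    v <- v / sqrt(sum(v^2))
    meas <- armspot:::quat_normalize(rnorm(4))[2:4]
    meas <- meas / sqrt(sum(meas^2))
    Fobj <- function(qq) {
      f <- armspot:::quat_rotate(armspot:::quat_conjugate(qq), v) - meas
      0.5 * sum(f^2)
    }
    num <- vapply(1:4, function(j) {
      e <- rep(0, 4); e[j] <- 1e-6
      (Fobj(q + e) - Fobj(q - e)) / 2e-6
    }, numeric(1))
    ana <- armspot:::grad_body_align(q[1], q[2:4], v, meas)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("static recordings fuse to a constant elevation after warm-up", {
  rec <- static_recording(150)
  fit <- estimate_orientation(rec)
  after <- fit$theta[fit$t >= 1]
  expect_lt(max(after) - min(after), 0.5)
  expect_lt(max(abs(after)), 1)  # truth is 0 deg (hanging)
  # accel-only and filtered agree on static data
  expect_lt(max(abs(fit$theta[fit$t >= 1] - fit$theta_accel[fit$t >= 1])), 1)
  # 3-4-5 rate magnitude
  rec2 <- imu_recording(accel = matrix(c(1, 0, 0), 2, 3, byrow = TRUE),
                        gyro = matrix(c(300, 400, 0), 2, 3, byrow = TRUE),
                        mag = matrix(c(0.87, 0, 0.5), 2, 3, byrow = TRUE))
  expect_equal(rate_magnitude(rec2), c(500, 500))
})

test_that("fusion tracks simulated throws where accel-only fails", {
  out <- throws_session()
  rec <- out$recording
  fit <- estimate_orientation(rec)
  truth <- out$truth
  # whole-session tracking
  expect_lt(sqrt(mean((fit$theta - truth$theta)^2)), 3)
  # around the ball-release impulses the accelerometer-only estimate is
  # corrupted by linear acceleration while the fused estimate holds on
  sel <- unlist(lapply(truth$events$peak_time,
                       function(p) which(abs(rec$t - p) < 0.5)))
  rms_filtered <- sqrt(mean((fit$theta[sel] - truth$theta[sel])^2))
  rms_accel <- sqrt(mean((fit$theta_accel[sel] - truth$theta[sel])^2))
  expect_lt(rms_filtered, 3)
  expect_gt(rms_accel, rms_filtered)
  # no post-impulse divergence: the last rest stretch is still tracked
  tail_sel <- which(rec$t > max(truth$events$peak_time) + 3)
  expect_lt(sqrt(mean((fit$theta[tail_sel] - truth$theta[tail_sel])^2)), 3)
})
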