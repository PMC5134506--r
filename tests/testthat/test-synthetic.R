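test_that("a rest-only script with zero noise yields a static recording", {
  nz <- sensor_noise(gyro_sd = 0, accel_sd = 0, mag_sd = 0, gyro_bias_max = 0)
  out <- generate_session(session_script(list(rest = 1), seed = 2), noise = nz)
  rec <- out$recording
  expect_lt(max(rate_magnitude(rec)), 1e-6)
  expect_equal(sqrt(rowSums(rec$accel^2)), rep(1, length(rec$t)),
               tolerance = 1e-9)
  fit <- estimate_orientation(rec)
  expect_lt(max(fit$theta) - min(fit$theta), 0.1)
  expect_equal(out$truth$theta, rep(out$truth$theta[1], length(rec$t)),
               tolerance = 1e-9)
})

test_that("generation is byte-identical under the same seed", {
  s <- session_script(list(baseball_throw = 2, flexion = 2), seed = 9)
  a <- generate_session(s)
  b <- generate_session(s)
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth$events, b$truth$events)
  c_ <- generate_session(session_script(list(baseball_throw = 2, flexion = 2),
                                        seed = 10))
  expect_false(identical(a$recording$gyro, c_$recording$gyro))
})

test_that("ground truth counts match the script and events are separable", {
  s <- session_script(list(baseball_throw = 5, volleyball_serve = 3,
                           scapular_punch = 4), seed = 12)
  out <- generate_session(s)
  expect_equal(out$truth$counts[["baseball_throw"]], 5L)
  expect_equal(out$truth$counts[["volleyball_serve"]], 3L)
  expect_equal(out$truth$counts[["scapular_punch"]], 4L)
  expect_equal(nrow(out$truth$events), 12L)
  # every consecutive pair of events is separated by more than 1 s
  expect_true(all(diff(out$truth$events$peak_time) > 1))
})

test_that("the emitted gyro is the derivative of the true orientation", {
  nz <- sensor_noise(gyro_sd = 0, accel_sd = 0, mag_sd = 0, gyro_bias_max = 0)
  out <- generate_session(session_script(list(baseball_throw = 3,
                                              volleyball_serve = 3),
                                         seed = 23), noise = nz)
  # central-difference body rate from the oversampled true trajectory (the
  # 50 Hz grid itself is too coarse to resolve a 2000 deg/s swing's rate)
  qf <- out$truth$q_fine
  fsf <- out$truth$fs_fine
  over <- as.integer(fsf / out$recording$fs)
  nf <- nrow(qf)
  mid <- 2:(nf - 1)
  qdot <- (qf[mid + 1, ] - qf[mid - 1, ]) * (fsf / 2)
  wq <- armspot:::quat_multiply(armspot:::quat_conjugate(qf[mid, ]), qdot)
  gyro_fd <- 2 * wq[, 2:4] * 180 / pi
  # compare at the common 50 Hz samples
  at <- seq(over + 1L, nf - over, by = over)
  idx50 <- (at - 1L) / over + 1L
  err <- sqrt(rowSums((out$recording$gyro[idx50, ] - gyro_fd[at - 1L, ])^2))
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("sports and exercises occupy the intended kinematic envelopes", {
  nz <- sensor_noise(gyro_sd = 0, accel_sd = 0, mag_sd = 0, gyro_bias_max = 0)
  out <- generate_session(session_script(
    list(baseball_throw = 4, volleyball_serve = 4), seed = 3), noise = nz)
  ev <- out$truth$events
  throws <- ev[ev$activity == "baseball_throw", ]
  serves <- ev[ev$activity == "volleyball_serve", ]
  expect_true(all(throws$peak_rate > 1500))
  expect_true(all(throws$peak_rate < 2800))
  expect_true(all(serves$peak_rate > 700))
  expect_true(all(serves$peak_rate < throws$peak_rate))
  # exercises never cross the stage-1 envelope even at high subject scale
  exo <- generate_session(
    session_script(as.list(stats::setNames(
      rep(2L, 7), setdiff(activity_templates(),
                          c("baseball_throw", "volleyball_serve", "rest"))),
    ), seed = 4, subject_scale = 1.15), noise = nz)
  fit <- estimate_orientation(exo$recording)
  hot <- fit$theta > 45 & fit$rate_mag > 400
  expect_equal(sum(hot), 0L)
})

test_that("gyro saturation clips per axis when enabled", {
  s <- session_script(list(baseball_throw = 2), seed = 6)
  clipped <- generate_session(s, noise = sensor_noise(clip_dps = 2000))
  expect_lte(max(abs(clipped$recording$gyro)), 2000)
  free <- generate_session(s, noise = sensor_noise())
  expect_gt(max(abs(free$recording$gyro)), 2000)
})

test_that("the benchmark suite mirrors the two-session protocol", {
  suite <- default_benchmark_suite(seed = 5)
  expect_length(suite$control, 11L)
  expect_length(suite$randomized, 11L)
  for (s in suite$control)
    expect_true(all(s$activities == 8L))
  for (s in suite$randomized) {
    sport <- s$activities[names(s$activities) %in%
                            c("baseball_throw", "volleyball_serve")]
    exercise <- s$activities[!names(s$activities) %in%
                               c("baseball_throw", "volleyball_serve")]
    expect_length(sport, 2L)
    expect_true(all(sport >= 4L & sport <= 12L))
    expect_true(all(exercise >= 2L & exercise <= 6L))
    expect_true(s$subject_scale >= 0.85 && s$subject_scale <= 1.15)
  }
  # a different master seed shuffles orders but keeps the rep bounds
  suite2 <- default_benchmark_suite(seed = 6)
  orders1 <- vapply(suite$randomized, function(s)
    paste(names(s$activities), collapse = ","), character(1))
  orders2 <- vapply(suite2$randomized, function(s)
    paste(names(s$activities), collapse = ","), character(1))
  expect_false(all(orders1 == orders2))
})

test_that("unknown activities and degenerate scripts are rejected", {
  expect_error(session_script(list(juggling = 3)), "unknown activity")
  expect_error(session_script(list(rest = 0)), ">= 1")
  expect_error(session_script(list(rest = 1), rep_gap = 0.5), ">= 1 s")
})
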