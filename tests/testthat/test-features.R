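# Build a synthetic segment directly (bypassing extraction) so feature
# values can be controlled exactly.
make_segment <- function(gyro, accel = NULL, elev = NULL, fs = 50) {
  n <- nrow(gyro)
  if (is.null(accel)) accel <- matrix(rep(c(1, 0, 0), each = n), n)
  if (is.null(elev)) elev <- matrix(rep(c(0, 90, 90), each = n), n)
  structure(list(accel = accel, gyro = gyro, mag = matrix(0.9, n, 3),
                 elev = elev, theta = elev[, 1], rate_mag = sqrt(rowSums(gyro^2)),
                 fs = fs, t_start = 0, trigger_offset = n %/% 2L,
                 padded = FALSE),
            class = "imu_segment")
}

test_that("the registry has 81 stable names including the reduced set", {
  reg <- feature_registry()
  expect_length(reg, 81L)
  expect_false(anyDuplicated(reg) > 0)
  expect_true(all(default_feature_set() %in% reg))
  expect_length(default_feature_set(), 8L)
  fv <- compute_features(make_segment(matrix(rnorm(300), 100)))
  expect_identical(names(fv), reg)
  expect_true(all(is.finite(fv)))
})

test_that("coarse FFT bands partition (0, 25] Hz once; fine bands nest", {
  bands <- armspot:::FFT_BANDS
  coarse <- bands[armspot:::FFT_COARSE, , drop = FALSE]
  o <- order(coarse[, 1])
  expect_equal(coarse[o, 1][1], 0)
  expect_equal(coarse[o, 2][nrow(coarse)], 25)
  expect_equal(coarse[o, 1][-1], coarse[o, 2][-nrow(coarse)])  # contiguous
  fine <- bands[-armspot:::FFT_COARSE, , drop = FALSE]
  for (i in seq_len(nrow(fine)))
    expect_true(any(fine[i, 1] >= coarse[, 1] & fine[i, 2] <= coarse[, 2]))
})

test_that("degenerate all-zero gyro yields zero rate features and null axis", {
  fv <- compute_features(make_segment(matrix(0, 100, 3)))
  expect_equal(unname(fv[sprintf("gyro_%s_%s", rep(c("x", "y", "z"), each = 4),
                                 c("min", "max", "range", "median"))]),
               rep(0, 12))
  expect_equal(unname(fv[c("rotaxis_x", "rotaxis_y", "rotaxis_z")]), c(0, 0, 0))
})

test_that("a DC z-rotation puts its energy in the lowest z band", {
  gyro <- matrix(rep(c(0, 0, 100), each = 100), 100)
  fv <- compute_features(make_segment(gyro))
  expect_equal(unname(fv[c("rotaxis_x", "rotaxis_y", "rotaxis_z")]), c(0, 0, 1))
  zbands <- grep("^fft_gyro_z_", feature_registry(), value = TRUE)
  dc <- "fft_gyro_z_0_0.5"
  expect_true(all(fv[dc] > fv[setdiff(zbands, dc)]))
})

test_that("a pure 7 Hz y tone lands in the 5-10 Hz band, not 10-25", {
  t <- (0:99) / 50
  gyro <- cbind(0, 200 * sin(2 * pi * 7 * t), 0)
  fv <- compute_features(make_segment(gyro))
  expect_gt(fv[["fft_gyro_y_5_10"]], 10 * fv[["fft_gyro_y_10_25"]])
  # rotation axis at peak rate is the y axis (sign-free check)
  expect_equal(abs(unname(fv["rotaxis_y"])), 1, tolerance = 1e-9)
})

test_that("band means are invariant under circular time shifts", {
  set.seed(12)
  gyro <- matrix(rnorm(300, 0, 50), 100)
  seg <- make_segment(gyro)
  fv <- compute_features(seg)
  band_names <- grep("^fft_", feature_registry(), value = TRUE)
  for (shift in c(7, 31)) {
    rolled <- gyro[c((shift + 1):100, 1:shift), ]
    fv2 <- compute_features(make_segment(rolled))
    expect_lt(max(abs(fv2[band_names] - fv[band_names])), 1e-9)
  }
})

test_that("feature extraction is deterministic and rejects short segments", {
  seg <- make_segment(matrix(rnorm(300), 100))
  expect_identical(compute_features(seg), compute_features(seg))
  expect_error(compute_features(make_segment(matrix(0, 1, 3))), "short")
})

test_that("forward selection finds the informative pair among noise", {
  set.seed(61)
  n <- 120
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 40), n, dimnames = list(NULL, paste0("f", 1:40)))
  # complementary informatives: f3 separates one half of each class, f17 the
  # other half, so either alone is ~75% and only the pair is separable
  half <- rep(rep(c(TRUE, FALSE), each = n / 4), 2)
  sgn <- ifelse(y == "A", 3, -3)
  X[half, "f3"] <- sgn[half] + rnorm(sum(half), 0, 0.3)
  X[!half, "f17"] <- sgn[!half] + rnorm(sum(!half), 0, 0.3)
  sel <- forward_select(X, y, k = 3, seed = 5)
  expect_true(all(c("f3", "f17") %in% sel[1:2]))
})

test_that("forward selection respects k = 0 and stops at a plateau", {
  set.seed(62)
  y <- rep(c("A", "B"), each = 30)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("f", 1:5)))
  X[, "f1"] <- ifelse(y == "A", 5, -5) + rnorm(60, 0, 0.1)  # alone perfect
  expect_length(forward_select(X, y, k = 0), 0L)
  sel <- forward_select(X, y, k = 4, seed = 5)
  expect_lt(length(sel), 4L)  # accuracy 1.0 after f1: no further additions
  expect_equal(sel[1], "f1", ignore_attr = TRUE)
  expect_error(forward_select(X, rep("A", 60), k = 2), "two classes")
  # deterministic given the seed
  expect_identical(as.character(forward_select(X, y, k = 3, seed = 9)),
                   as.character(forward_select(X, y, k = 3, seed = 9)))
})
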