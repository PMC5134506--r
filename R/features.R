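# Per-segment feature extraction. Each fixed-width segment yields 81 named
# scalars:
#   (i)   min / max / range / median of acceleration, rotation rate, and
#         per-axis elevation relative to gravity, for all three device axes
#         (3 channels x 3 axes x 4 stats = 36);
#   (ii)  the rotation-rate vector at the sample of maximum arm elevation (3);
#   (iii) the unit rotation-axis components at the sample of maximum
#         rotation-rate magnitude (3);
#   (iv)  mean FFT magnitudes of the rotation rate in 13 fixed frequency
#         bands per axis (39).
# The band set is multi-resolution: six coarse contiguous bands partition
# (0, 25] Hz exactly once -- 0-0.5, 0.5-1.5, 1.5-2.5, 2.5-5, 5-10 and
# 10-25 Hz, so every band used by the reduced 8-feature classifier is a
# single feature -- and seven finer sub-bands (5-7.5, 7.5-10, 10-12.5,
# 12.5-15, 15-17.5, 17.5-20, 20-25 Hz) refine the two wide bands.

FFT_BANDS <- rbind(
  c(0, 0.5), c(0.5, 1.5), c(1.5, 2.5), c(2.5, 5), c(5, 10), c(10, 25),
  c(5, 7.5), c(7.5, 10), c(10, 12.5), c(12.5, 15), c(15, 17.5), c(17.5, 20),
  c(20, 25)
)
FFT_COARSE <- 1:6  # rows of FFT_BANDS forming the exact partition of (0,25]

AXES <- c("x", "y", "z")

band_name <- function(axis, lo, hi) {
  sprintf("fft_gyro_%s_%g_%g", axis, lo, hi)
}

#' Feature registry
#'
#' The 81 feature names in their stable order. Includes, by name, the eight
#' features used by the reduced classifier: `rotaxis_x`, `rotaxis_z`,
#' `elev_x_range`, `fft_gyro_y_5_10`, `fft_gyro_y_10_25`, `fft_gyro_z_0_0.5`,
#' `fft_gyro_z_2.5_5` and `fft_gyro_x_0.5_1.5`.
#'
#' @return Character vector of length 81.
#' @export
feature_registry <- function() {
  stats <- c("min", "max", "range", "median")
  group1 <- as.vector(vapply(c("accel", "gyro", "elev"), function(ch)
    vapply(AXES, function(ax) paste(ch, ax, stats, sep = "_"),
           character(4L)), character(12L)))
  group2 <- paste0("gyro_at_peak_elev_", AXES)
  group3 <- paste0("rotaxis_", AXES)
  group4 <- as.vector(vapply(AXES, function(ax)
    band_name(ax, FFT_BANDS[, 1L], FFT_BANDS[, 2L]),
    character(nrow(FFT_BANDS))))
  c(group1, group2, group3, group4)
}

#' The reduced eight-feature set
#'
#' The feature subset the reduced classifier runs on: the X and Z components
#' of the rotation axis at peak rotation rate, the X-axis range of motion
#' relative to gravity, and the mean rotation-rate FFT magnitudes in the
#' Y 5-10 Hz, Y 10-25 Hz, Z 0-0.5 Hz, Z 2.5-5 Hz and X 0.5-1.5 Hz bands.
#'
#' @return Character vector of length 8 (a subset of [feature_registry()]).
#' @export
default_feature_set <- function() {
  c("rotaxis_x", "rotaxis_z", "elev_x_range",
    band_name("y", 5, 10), band_name("y", 10, 25),
    band_name("z", 0, 0.5), band_name("z", 2.5, 5),
    band_name("x", 0.5, 1.5))
}

# Mean FFT magnitude per band for one axis. Magnitudes are |fft(x)| / n over
# the non-negative frequencies; a band [lo, hi) averages the bins whose
# center frequency falls in it, with the Nyquist bin folded into bands whose
# upper edge is the Nyquist frequency.
fft_band_means <- function(x, fs, bands = FFT_BANDS) {
  n <- length(x)
  mags <- Mod(stats::fft(x)) / n
  k <- 0:(n %/% 2L)
  freq <- k * fs / n
  mags <- mags[k + 1L]
  nyq <- fs / 2
  vapply(seq_len(nrow(bands)), function(b) {
    lo <- bands[b, 1L]; hi <- bands[b, 2L]
    sel <- freq >= lo & (freq < hi | (hi >= nyq & freq == nyq))
    if (!any(sel)) return(0)
    mean(mags[sel])
  }, numeric(1L))
}

#' Compute the 81-value feature vector of a segment
#'
#' @param seg An [extract_segment()] result.
#' @return Named numeric vector of length 81 in [feature_registry()] order.
#'   The rotation axis is the unit-normalized gyro vector at the peak-rate
#'   sample, or `(0, 0, 0)` when the peak rate is below 1 deg/s.
#' @export
compute_features <- function(seg) {
  stopifnot(inherits(seg, "imu_segment"))
  n <- length(seg$theta)
  if (n < 2L)
    stop("segment too short for feature extraction (need >= 2 samples)",
         call. = FALSE)
  stat4 <- function(v) c(min(v), max(v), max(v) - min(v), stats::median(v))
  group1 <- unlist(lapply(list(seg$accel, seg$gyro, seg$elev), function(m)
    as.vector(apply(m, 2L, stat4))))
  i_elev <- which.max(seg$theta)
  group2 <- seg$gyro[i_elev, ]
  i_rate <- which.max(seg$rate_mag)
  peak <- seg$rate_mag[i_rate]
  group3 <- if (peak < 1) c(0, 0, 0) else seg$gyro[i_rate, ] / peak
  group4 <- as.vector(vapply(1:3, function(ax)
    fft_band_means(seg$gyro[, ax], seg$fs), numeric(nrow(FFT_BANDS))))
  fv <- c(group1, group2, group3, group4)
  names(fv) <- feature_registry()
  if (any(!is.finite(fv)))
    stop("non-finite feature value(s) computed", call. = FALSE)
  fv
}

#' Featurize detections of a recording
#'
#' Extracts a fixed window around each detection and computes its feature
#' vector.
#'
#' @param rec An [imu_recording()].
#' @param fit Matching [estimate_orientation()] fit.
#' @param events A [spot_gestures()] result (or any data.frame with an
#'   `index` column).
#' @param window,pre_share Passed to [extract_segment()].
#' @return Numeric matrix, one row per event, 81 named columns.
#' @export
featurize_events <- function(rec, fit, events, window = 2.0, pre_share = 0.4) {
  if (!nrow(events))
    return(matrix(numeric(), 0L, 81L, dimnames = list(NULL, feature_registry())))
  t(vapply(events$index, function(i)
    compute_features(extract_segment(rec, fit, i, window, pre_share)),
    numeric(81L)))
}

#' Forward sequential feature selection
#'
#' Greedy wrapper selection for the stage-2 bagged-tree classifier: starting
#' from the empty set, repeatedly add the feature that maximizes stratified
#' k-fold cross-validated accuracy, until `k` features are selected or no
#' candidate improves the accuracy. Deterministic given `seed`.
#'
#' @param X Numeric feature matrix with named columns (rows = segments).
#' @param y Class labels (factor or character), length `nrow(X)`.
#' @param k Target number of features (default 8).
#' @param seed Integer seed controlling fold assignment and tree growth.
#' @param ntree Trees per candidate ensemble during selection (default 50;
#'   smaller than the final classifier for speed).
#' @param folds Number of cross-validation folds (default 5).
#' @return Character vector of selected feature names (class
#'   `selected_features`), with the cross-validated accuracy after each
#'   addition in `attr(, "cv_accuracy")`.
#' @export
forward_select <- function(X, y, k = 8, seed = 1, ntree = 50, folds = 5) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("feature selection needs at least two classes", call. = FALSE)
  if (k > ncol(X))
    stop("k cannot exceed the number of candidate features", call. = FALSE)
  if (k == 0L)
    return(structure(character(), cv_accuracy = numeric(),
                     class = c("selected_features", "character")))
  y <- droplevels(y)
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  cv_acc <- function(feats) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L) next
      set.seed(seed + 7919L * f)
      fit <- randomForest::randomForest(
        x = X[tr, feats, drop = FALSE], y = y[tr],
        ntree = ntree, mtry = length(feats), replace = TRUE)
      pred <- predict(fit, X[!tr, feats, drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }
  selected <- character()
  acc_path <- numeric()
  best_acc <- -Inf
  for (step in seq_len(k)) {
    candidates <- setdiff(colnames(X), selected)
    accs <- vapply(candidates, function(f) cv_acc(c(selected, f)), numeric(1L))
    i <- which.max(accs)
    if (accs[i] <= best_acc + 1e-12) break  # plateau: no improvement
    selected <- c(selected, candidates[i])
    best_acc <- accs[i]
    acc_path <- c(acc_path, best_acc)
  }
  structure(selected, cv_accuracy = acc_path,
            class = c("selected_features", "character"))
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> %d feature(s)\n", length(x)))
  acc <- attr(x, "cv_accuracy")
  for (i in seq_along(x))
    cat(sprintf("  %d. %-24s cv accuracy %.3f\n", i, x[i], acc[i]))
  invisible(x)
}
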