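# Stage-2 classification. A bootstrap-aggregated ensemble of 160 unpruned
# decision trees (bagging = random forest with mtry equal to the number of
# features) scores each extracted segment; the per-class score is the vote
# fraction across trees. A segment is counted as a Throw or Serve only if
# its best sport-class score is at least the posterior threshold (0.60);
# otherwise it falls into the Neither (null) class.

GESTURE_CLASSES <- c("Throw", "Serve", "Neither")
SPORT_CLASSES <- c("Throw", "Serve")

#' Train the gesture classifier
#'
#' Splits the data into a stratified 40/60 train/test partition (the held-out
#' 60% is recorded in the model for evaluation), then fits a bagged ensemble
#' of `trees` decision trees on the training rows. Bootstrap resamples are
#' the size of the training set; trees are unpruned with the default split
#' criterion.
#'
#' @param X Numeric feature matrix with named columns, one row per segment.
#' @param y Labels: `"Throw"`, `"Serve"` or `"Neither"` (any >= 2 classes
#'   with >= 2 members each are accepted).
#' @param features Feature subset to train on (default
#'   [default_feature_set()]); use `colnames(X)` for all.
#' @param trees Ensemble size (default 160).
#' @param train_frac Fraction of rows used for training (default 0.4).
#' @param seed Integer seed; fixes both the stratified split and tree growth,
#'   so the same seed reproduces the model exactly.
#' @return An object of class `gesture_model`: list with the fitted `forest`,
#'   `features`, `classes`, `train_idx`, `test_idx`, `trees`, `train_frac`,
#'   `seed`.
#' @export
train_gesture_model <- function(X, y, features = default_feature_set(),
                                trees = 160, train_frac = 0.4, seed = 1) {
  y <- factor(as.character(y))
  if (nrow(X) != length(y))
    stop("X and y must have matching lengths", call. = FALSE)
  if (nrow(X) < 10L)
    stop("need at least 10 labelled segments to train", call. = FALSE)
  if (nlevels(y) < 2L)
    stop("training requires at least two classes", call. = FALSE)
  if (any(table(y) < 2L))
    stop(sprintf("class '%s' has fewer than 2 examples",
                 names(which(table(y) < 2L))[1L]), call. = FALSE)
  missing <- setdiff(features, colnames(X))
  if (length(missing))
    stop(sprintf("feature(s) absent from X: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  set.seed(seed)
  train_idx <- integer()
  for (cl in levels(y)) {
    rows <- which(y == cl)
    n_tr <- max(1L, round(train_frac * length(rows)))
    train_idx <- c(train_idx, sort(sample(rows, n_tr)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(X)), train_idx)
  set.seed(seed + 104729L)
  forest <- randomForest::randomForest(
    x = X[train_idx, features, drop = FALSE],
    y = droplevels(y[train_idx]),
    ntree = trees, mtry = length(features), replace = TRUE)
  structure(list(forest = forest, features = features,
                 classes = levels(droplevels(y[train_idx])),
                 train_idx = train_idx, test_idx = test_idx,
                 y = y, trees = trees, train_frac = train_frac, seed = seed),
            class = "gesture_model")
}

#' @export
print.gesture_model <- function(x, ...) {
  cat(sprintf("<gesture_model> %d bagged trees on %d features, classes: %s\n",
              x$trees, length(x$features), paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d segments (%.0f%%), %d held out\n",
              length(x$train_idx), 100 * x$train_frac, length(x$test_idx)))
  invisible(x)
}

#' Per-class vote-fraction scores
#'
#' Fraction of the ensemble's trees voting for each class; scores are
#' non-negative and sum to one per segment.
#'
#' @param model A [train_gesture_model()] fit.
#' @param X Feature matrix (or single named feature vector) containing the
#'   model's feature subset.
#' @return Numeric matrix, one row per segment, one named column per trained
#'   class.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "gesture_model"))
  if (!is.matrix(X)) X <- matrix(X, 1L, dimnames = list(NULL, names(X)))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing))
    stop(sprintf("feature(s) missing from input: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  v <- predict(model$forest, X[, model$features, drop = FALSE],
               type = "vote", norm.votes = TRUE)
  v <- matrix(v, nrow = nrow(X), ncol = ncol(v),
              dimnames = list(NULL, colnames(v)))
  v
}

#' @export
predict.gesture_model <- function(object, newdata,
                                  threshold = 0.60, ...) {
  scores <- predict_scores(object, newdata)
  decide_class(scores, threshold)
}

#' Null-class decision rule
#'
#' A segment is assigned to the sport class (Throw or Serve) with the
#' highest score provided that score is at least `threshold` ("at least 60%
#' probability", so the comparison is inclusive); otherwise it is Neither.
#'
#' @param scores Score matrix from [predict_scores()] (or a single named
#'   score vector).
#' @param threshold Posterior score threshold (default 0.60).
#' @return Character vector of `"Throw"`, `"Serve"` or `"Neither"`.
#' @examples
#' decide_class(c(Throw = 0.9, Serve = 0.1))            # "Throw"
#' decide_class(c(Throw = 0.55, Serve = 0.45))          # "Neither"
#' decide_class(c(Throw = 0.60, Serve = 0.40))          # boundary: "Throw"
#' @export
decide_class <- function(scores, threshold = 0.60) {
  if (!is.matrix(scores))
    scores <- matrix(scores, 1L, dimnames = list(NULL, names(scores)))
  sport <- intersect(SPORT_CLASSES, colnames(scores))
  if (!length(sport))
    stop("scores carry no sport class columns", call. = FALSE)
  s <- scores[, sport, drop = FALSE]
  best <- sport[apply(s, 1L, which.max)]
  ifelse(apply(s, 1L, max) >= threshold, best, "Neither")
}

#' Run the full two-stage pipeline on a recording
#'
#' Orientation fusion, stage-1 spotting, fixed-window segment extraction,
#' feature computation, ensemble scoring and the null-class decision, applied
#' causally in sequence. Throw and Serve decisions are counted; Neither
#' detections are reported but not counted.
#'
#' @param rec An [imu_recording()].
#' @param model A [train_gesture_model()] fit.
#' @param rule Stage-1 [detection_rule()].
#' @param cfg [fusion_config()] for the fusion stage.
#' @param window,pre_share Segment extraction geometry.
#' @param threshold Null-class posterior threshold (default 0.60).
#' @return An object of class `pipeline_result`: list with `events` (a
#'   data.frame of time, decided class and per-class scores) and `counts`
#'   (named integer vector over Throw and Serve).
#' @export
run_pipeline <- function(rec, model, rule = detection_rule(),
                         cfg = fusion_config(), window = 2.0,
                         pre_share = 0.4, threshold = 0.60) {
  stopifnot(inherits(model, "gesture_model"))
  empty <- list(
    events = data.frame(time = numeric(), class = character()),
    counts = c(Throw = 0L, Serve = 0L))
  if (length(rec$t) < 2L)
    return(structure(empty, class = "pipeline_result"))
  fit <- estimate_orientation(rec, cfg)
  events <- spot_gestures(fit$theta, fit$rate_mag, rule, rec$fs, rec$t)
  if (!nrow(events))
    return(structure(empty, class = "pipeline_result"))
  X <- featurize_events(rec, fit, events, window, pre_share)
  scores <- predict_scores(model, X)
  cls <- decide_class(scores, threshold)
  out <- data.frame(time = events$time, class = cls,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  counts <- c(Throw = sum(cls == "Throw"), Serve = sum(cls == "Serve"))
  structure(list(events = out, counts = counts),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d detection(s): %d Throw, %d Serve, %d Neither\n",
              nrow(x$events), x$counts[["Throw"]], x$counts[["Serve"]],
              sum(x$events$class == "Neither")))
  invisible(x)
}

#' Save / load a gesture model
#'
#' Single-file persistence with the training configuration and seed embedded;
#' a reloaded model yields identical predictions.
#'
#' @param model A `gesture_model`.
#' @param path File path.
#' @return `read_gesture_model` returns the model; `write_gesture_model`
#'   returns `path` invisibly.
#' @name model_io
#' @export
write_gesture_model <- function(model, path) {
  stopifnot(inherits(model, "gesture_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname model_io
#' @export
read_gesture_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gesture_model"))
    stop("file does not contain a gesture_model", call. = FALSE)
  model
}
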