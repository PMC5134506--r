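# Building labelled training data from ground-truthed sessions.
#
# Throw/Serve examples are the segments the deployed (strict) stage-1 rule
# would extract around true sport repetitions. Null-class examples cannot be
# harvested with that rule -- it is designed to reject exercises -- so the
# Neither class is populated by running a loosened rule (same elevation
# threshold, lower rate threshold) and keeping the detections that match no
# sport repetition. This mirrors how false detections would enter a
# classifier's null class in deployment.

#' Build a labelled feature matrix from simulated sessions
#'
#' Runs orientation fusion and stage-1 spotting on each session, extracts
#' fixed windows, computes the 81-value feature vector per detection, and
#' labels each detection by the ground-truth repetition whose peak-rate time
#' is nearest (within `match_tol` seconds): sport repetitions give `Throw` /
#' `Serve`, everything else `Neither`.
#'
#' @param sessions List of [generate_session()] results.
#' @param rule Deployed stage-1 [detection_rule()] for sport segments.
#' @param loose_rule Loosened rule used to harvest null-class segments
#'   (default: rate threshold lowered to 150 deg/s).
#' @param cfg [fusion_config()].
#' @param window,pre_share Segment geometry, as in [extract_segment()].
#' @param match_tol Maximum |detection - truth peak| gap to accept a label
#'   match, seconds.
#' @return List with `X` (feature matrix, 81 named columns), `y` (character
#'   labels) and `session` (integer session index per row).
#' @export
build_training_set <- function(sessions, rule = detection_rule(),
                               loose_rule = detection_rule(rate_threshold = 150),
                               cfg = fusion_config(), window = 2.0,
                               pre_share = 0.4, match_tol = 1.0) {
  Xs <- list(); ys <- character(); sid <- integer()
  for (si in seq_along(sessions)) {
    ses <- sessions[[si]]
    rec <- ses$recording
    fit <- estimate_orientation(rec, cfg)
    events <- spot_gestures(fit$theta, fit$rate_mag, loose_rule, rec$fs, rec$t)
    if (!nrow(events)) next
    strict <- spot_gestures(fit$theta, fit$rate_mag, rule, rec$fs, rec$t)
    truth <- ses$truth$events
    lab <- character(nrow(events))
    keep <- logical(nrow(events))
    for (i in seq_len(nrow(events))) {
      dt <- abs(truth$peak_time - events$time[i])
      j <- which.min(dt)
      matched <- length(j) == 1L && dt[j] <= match_tol
      if (matched && truth$sport[j]) {
        # sport segments must also be what the deployed rule would extract
        near_strict <- nrow(strict) &&
          any(abs(strict$time - events$time[i]) <= match_tol)
        if (!near_strict) next
        lab[i] <- if (truth$activity[j] == "baseball_throw") "Throw"
                  else "Serve"
      } else {
        lab[i] <- "Neither"
      }
      keep[i] <- TRUE
    }
    if (!any(keep)) next
    X <- featurize_events(rec, fit, events[keep, , drop = FALSE],
                          window, pre_share)
    Xs[[length(Xs) + 1L]] <- X
    ys <- c(ys, lab[keep])
    sid <- c(sid, rep(si, sum(keep)))
  }
  if (!length(Xs))
    stop("no labelled segments were produced from the sessions", call. = FALSE)
  list(X = do.call(rbind, Xs), y = ys, session = sid)
}
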